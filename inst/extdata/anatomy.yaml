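# Anatomical parameter tables for the published mouse visual cortex
# network configuration. Densities are excitatory-only; voxel counts are
# (10 um)^3 voxels from the CCFv3 parcellation; interlaminar widths are
# cat-cortex values to be scaled by the mouse L4->L4 anchor; d75 are
# pairwise connection probabilities at 75 um horizontal offset; areas are
# flat-map convex-hull surface areas in mm^2.
version: 1
densities:            # excitatory neurons / mm^3, measured areas only
  VISp:  {L4: 106114.7, L2/3: 86668.2, L5: 86643.4}
  VISal: {L4: 93176.9,  L2/3: 79070.6, L5: 78540.9}
  VISl:  {L4: 86559.9,  L2/3: 73937.9, L5: 66215.6}
  VISpl: {L4: 106783.0, L2/3: 87368.3, L5: 82538.1}
# areas without their own density measurements use the average of the four above
density_average_areas: [VISrl, VISli, VISpor]
voxel_counts:         # number of 10-um voxels per region
  VISp:   {L4: 1023640, L2/3: 1999040, L5: 1552688}
  VISal:  {L4: 104152,  L2/3: 199314,  L5: 202942}
  VISl:   {L4: 179084,  L2/3: 301588,  L5: 314522}
  VISpl:  {L4: 36638,   L2/3: 205150,  L5: 242812}
  VISrl:  {L4: 146294,  L2/3: 276390,  L5: 244294}
  VISli:  {L4: 57256,   L2/3: 117252,  L5: 147946}
  VISpor: {L4: 60632,   L2/3: 373972,  L5: 385168}
dlgn_count: 21200     # excitatory neuron count, dorsal lateral geniculate
interlaminar_widths_cat:  # Gaussian widths (um), cat V1, source x target
  L2/3: {L2/3: 225, L4: 50,  L5: 100}
  L4:   {L2/3: 220, L4: 180, L5: 140}
  L5:   {L2/3: 150, L4: 100, L5: 210}
width_scaling:
  mouse_ref: 114      # mouse L4->L4 functional-connection width (um)
  cat_ref: 180        # cat L4->L4 width (um)
interlaminar_d75:     # connection probability at 75 um offset, source x target
  L2/3: {L2/3: 0.160, L4: 0.016, L5: 0.083}
  L4:   {L2/3: 0.140, L4: 0.243, L5: 0.104}
  L5:   {L2/3: 0.021, L4: 0.007, L5: 0.116}
d75_offset_um: 75
areas_mm2:            # flat-map convex hull surface areas (mm^2)
  VISp:   {L4: 4.3271, L2/3: 4.7406, L5: 4.2511}
  VISal:  {L4: 0.4909, L2/3: 0.5477, L5: 0.4972}
  VISl:   {L4: 0.8793, L2/3: 0.9279, L5: 0.8651}
  VISli:  {L4: 0.3355, L2/3: 0.4356, L5: 0.4039}
  VISpl:  {L4: 0.2865, L2/3: 0.6659, L5: 0.6785}
  VISrl:  {L4: 0.6182, L2/3: 0.6980, L5: 0.6748}
  VISpor: {L4: 0.5264, L2/3: 1.3937, L5: 1.2445}
model:
  input_size: 64          # pixels; 1 pixel/degree acuity over ~64 degrees
  input_channels: 3
  post_visp_size: 32      # grid size of every region past VISp
  stride_from_visp: 2     # stride of edges outbound from VISp regions
  rf_dlgn_deg: 9          # receptive field, dLGN (degrees -> 9x9 kernel)
  rf_visp_deg: 11         # receptive field, VISp (-> 3x3 on top of 9x9)
  extrinsic_in_degree: 1000   # assumed interareal fan-in e
  n_classes: 1000
  classifier_pool: 4      # L5 outputs average-pooled to 4x4
# As-published conv meta-parameter table (kernel sizes, pixels). Interareal
# rows are the only source of interareal kernel sizes (the voxel-model
# profile estimates behind them are not recomputed here). Interlaminar rows
# serve as a verbatim override; the default build derives those from the
# width formula, which differs for exactly two cells (VISli4->VISli2/3
# printed 17 vs formula 15; VISpl4->VISpl2/3 printed 19 vs formula 17).
published_kernels:
  - {source: input,     target: dLGN,      k: 9}
  - {source: dLGN,      target: VISp4,     k: 3}
  - {source: VISp4,     target: VISp2/3,   k: 9}
  - {source: VISp4,     target: VISal4,    k: 17}
  - {source: VISp4,     target: VISl4,     k: 19}
  - {source: VISp4,     target: VISli4,    k: 19}
  - {source: VISp4,     target: VISpl4,    k: 19}
  - {source: VISp4,     target: VISrl4,    k: 19}
  - {source: VISp4,     target: VISpor4,   k: 17}
  - {source: VISp2/3,   target: VISp5,     k: 3}
  - {source: VISp2/3,   target: VISal4,    k: 15}
  - {source: VISp2/3,   target: VISl4,     k: 19}
  - {source: VISp2/3,   target: VISli4,    k: 17}
  - {source: VISp2/3,   target: VISpl4,    k: 17}
  - {source: VISp2/3,   target: VISrl4,    k: 21}
  - {source: VISp2/3,   target: VISpor4,   k: 19}
  - {source: VISp5,     target: VISal4,    k: 15}
  - {source: VISp5,     target: VISl4,     k: 19}
  - {source: VISp5,     target: VISli4,    k: 19}
  - {source: VISp5,     target: VISpl4,    k: 17}
  - {source: VISp5,     target: VISrl4,    k: 19}
  - {source: VISp5,     target: VISpor4,   k: 19}
  - {source: VISpor4,   target: VISpor2/3, k: 13}
  - {source: VISpor2/3, target: VISpor5,   k: 3}
  - {source: VISal4,    target: VISal2/3,  k: 13}
  - {source: VISal4,    target: VISpor4,   k: 3}
  - {source: VISal2/3,  target: VISal5,    k: 5}
  - {source: VISal2/3,  target: VISpor4,   k: 1}
  - {source: VISal5,    target: VISpor4,   k: 1}
  - {source: VISl4,     target: VISl2/3,   k: 9}
  - {source: VISl4,     target: VISpor4,   k: 15}
  - {source: VISl2/3,   target: VISl5,     k: 5}
  - {source: VISl2/3,   target: VISpor4,   k: 15}
  - {source: VISl5,     target: VISpor4,   k: 15}
  - {source: VISli4,    target: VISli2/3,  k: 17}
  - {source: VISli4,    target: VISpor4,   k: 17}
  - {source: VISli2/3,  target: VISli5,    k: 7}
  - {source: VISli2/3,  target: VISpor4,   k: 17}
  - {source: VISli5,    target: VISpor4,   k: 15}
  - {source: VISpl4,    target: VISpl2/3,  k: 19}
  - {source: VISpl4,    target: VISpor4,   k: 3}
  - {source: VISpl2/3,  target: VISpl5,    k: 5}
  - {source: VISpl2/3,  target: VISpor4,   k: 5}
  - {source: VISpl5,    target: VISpor4,   k: 5}
  - {source: VISrl4,    target: VISrl2/3,  k: 11}
  - {source: VISrl4,    target: VISpor4,   k: 7}
  - {source: VISrl2/3,  target: VISrl5,    k: 5}
  - {source: VISrl2/3,  target: VISpor4,   k: 9}
  - {source: VISrl5,    target: VISpor4,   k: 9}
# SYNTHETIC stand-in for the interareal Gaussian-profile table (the real
# per-edge aggregate connectome weights are not redistributable here).
# Interareal peak probabilities are derived at build time from the in-degree
# identity with equal inbound weight fractions per target; this flag records
# the provenance on every interareal edge.
interareal_profile: synthetic-equal-weights
# Unimodality filter defaults for interareal width estimation
flatmap:
  voxel_size_um: 100
  smooth_bandwidth_voxels: 1.0
  peak_threshold: 0.10
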