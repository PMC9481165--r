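# mvcnet

Connectome-constrained convolutional network models of mouse visual
cortex, in R.

Modern CNNs are routinely compared to visual cortex, but their
architectures — deep, serial, parameter-rich — look nothing like the
mouse visual system, which is shallow, parallel, and small. `mvcnet` is
for computational neuroscientists who want the opposite starting point:
it *compiles measured anatomy into a network*. Laminar excitatory-neuron
censuses fix how many channels each cortical layer gets, a voxel-level
interareal connectome fixes the spatial footprint of each projection,
and paired-recording statistics fix how densely layers connect — the
result is a fully specified sparse CNN whose every meta-parameter traces
back to a measurement, plus the representational-similarity toolbox used
to compare such models against population recordings.

## The model in brief

A *region* is one cortical layer of one area. The published
configuration has 22 regions (dLGN + {L4, L2/3, L5} of VISp, five
lateral areas, and VISpor) joined by 49 convolutional projections:
input → dLGN → VISp4, laminar flow L4 → L2/3 → L5 inside each area,
VISp fanning out to five parallel lateral pathways, and everything
converging on VISpor L4. For an edge from region *i* to region *j*:

- channels: `c_i = floor(n_i / (l_x l_y))`, with `n_i` the excitatory
  neuron count (density × volume);
- kernel: `k = 2 floor(sigma_i d_w) + 1`, where
  `sigma_i = sqrt(l_x l_y / a_i)` converts the Gaussian connection
  width `d_w` [µm] into source-grid pixels;
- sparsity: a binary mask sampled from
  `P(r) = min(1, d_p exp(-r² / 2 d̃_w²))`, with the peak `d_p` recovered
  from connection probabilities at 75 µm offset (interlaminar) or from
  an assumed in-degree of 1000 (interareal);
- runtime: each region applies one batch-norm + ReLU to the *sum* of its
  inbound convolutions; an average-pool + linear head reads out all L5
  outputs for classification. Masked weights stay exactly zero through
  training.

The package has six modules: `anatomy` (census arithmetic from the
shipped YAML tables), `flatmap` (sphere fit, 2D projection, convex-hull
areas, interareal Gaussian width/peak estimation from a voxel
connectome), `archgen` (the compiler itself plus parameter accounting),
`netruntime` (pure-R masked convolutions with a full backward pass),
`metrics` (SSM, split-half reliability, noise ceilings, lifetime
sparseness, circular selectivity, Jensen–Shannon distance, MDS layer
diversity), and `synthdata` (generators with known ground truth for
every stage). See the vignette in `vignettes/` for the science and the
design decisions.

## Worked example

```r
library(mvcnet)

cfg    <- load_anatomy_config()     # shipped published configuration
census <- region_census(cfg)
head(census, 4)
#>    area layer  density  voxels      n
#> 1  VISp    L4 106114.7 1023640 108623
#> 2  VISp  L2/3  86668.2 1999040 173253
#> 3  VISp    L5  86643.4 1552688 134530
#> 4 VISal    L4  93176.9  104152   9705
```

VISp L4 has ~108.6k excitatory neurons (density × voxel volume); on a
64×64 grid that yields floor(108623/4096) = 26 channels. The
interlaminar Gaussian statistics scale cat-cortex widths to mouse and
invert the 75-µm offset probabilities:

```r
subset(interlaminar_stats(cfg), source == "L4")
#>   source target cat_width        dw   d75        dp
#> 1     L4     L4       180 114.00000 0.243 0.3017124
#> 2     L4   L2/3       220 139.33333 0.140 0.1618247
#> 3     L4     L5       140  88.66667 0.104 0.1487303
```

So an L4 pair at zero offset connects with probability ~0.30, decaying
with a 114 µm width. Compiling the full graph:

```r
arch <- build_graph(cfg)
arch
#> <mvc_arch> 22 regions, 49 conv edges, classifier 2304 -> 1000 classes
head(summarize_architecture(arch), 4)
#>        source  target kernel stride padding
#> 1    input(3)    dLGN  9 x 9      1       4
#> 2     dLGN(5)   VISp4  3 x 3      1       1
#> 3   VISp4(26) VISp2/3  9 x 9      1       4
#> 4 VISp2/3(42)   VISp5  3 x 3      1       1

c(dense      = count_parameters(arch, "dense"),
  expected   = round(count_parameters(arch, "masked-expected")),
  sampled    = count_parameters(arch, "masked-sampled"),
  classifier = count_parameters(arch, "classifier"))
#>      dense   expected    sampled classifier
#>    2145097      59631      59672    2305000
```

The dense conv total rounds to 2.1M and the 1000-class classifier is
exactly 2,305,000 parameters; the Gaussian masks keep only ~60k conv
weights (the sampled count sits within binomial error of the expected
count). Running the network and extracting a layer representation:

```r
net  <- net_init(arch, seed = 1)
imgs <- gen_natural_images(8, 64, 3, seed = 2)   # 1/f-noise stand-ins
net  <- net_calibrate(net, imgs)                 # batch-norm statistics
R    <- extract_layer_activations(net, imgs, "VISp4")
dim(R)
#> [1]      8 106496                               # 26 x 64 x 64 per image
ssm(similarity_matrix(R), similarity_matrix(R))
#> [1] 1
```

A command-line interface wraps the same operations
(`inst/cli/mvcnet build | summarize | count-params | train |
activations | metrics | synth`), writing a JSON manifest with config
hash and seeds beside every output.

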