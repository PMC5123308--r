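# Independent oracles for the lineage-counting probability g_{i,j}(T).
#
# (1) hypoexp_cdf: the event {i lineages reach 1 within T} is the event
#     that a sum of independent exponentials (rates m(m-1)/2, m = i..2)
#     is at most T; its CDF has the classical partial-fraction closed
#     form.  Implemented directly from that form, sharing no code with
#     g_ij().  Double precision limits it to moderate probabilities.
#
# (2) G_ORACLE: values of g_{i,j}(T) evaluated from the spectral sum in
#     60-significant-digit arithmetic (mpmath), frozen here, covering
#     tiny probabilities where any double-precision route cancels.

hypoexp_cdf <- function(i, T) {
  if (i == 1) return(1)
  rates <- sapply(i:2, function(m) m * (m - 1) / 2)
  cdf <- 1
  for (m in seq_along(rates)) {
    c_m <- prod(rates[-m] / (rates[-m] - rates[m]))
    cdf <- cdf - c_m * exp(-rates[m] * T)
  }
  cdf
}

G_ORACLE <- local({
  tab <- c(
    "2 1 0.01 0.0099501662508319464",
    "2 1 0.1 0.095162581964040427",
    "2 1 0.2 0.18126924692201814",
    "2 1 0.5 0.39346934028736658",
    "2 1 1 0.63212055882855768",
    "2 1 2 0.86466471676338731",
    "2 1 5 0.99326205300091453",
    "3 1 0.01 0.00014801615050200811",
    "3 1 0.1 0.013152983286919573",
    "3 1 0.2 0.046309688430040428",
    "3 1 0.5 0.20176909050526478",
    "3 1 1 0.47307437242676849",
    "3 1 2 0.79823645123341414",
    "3 1 5 0.98989323245253205",
    "4 1 0.01 2.9260831559385921e-6",
    "4 1 0.1 0.0023485409981853478",
    "4 1 0.2 0.014857438171218668",
    "4 1 0.5 0.12141755899211688",
    "4 1 1 0.38710832382393449",
    "4 1 2 0.75887401350829285",
    "4 1 5 0.98787200130394795",
    "6 1 0.01 2.1229252848984988e-9",
    "6 1 0.1 0.00012801130943105461",
    "6 1 0.2 0.0024175712825760016",
    "6 1 0.5 0.058679611493847915",
    "6 1 1 0.29853648546290967",
    "6 1 2 0.71441704507316088",
    "6 1 5 0.98556208839888263",
    "8 1 0.01 2.837423426038335e-12",
    "8 1 0.1 1.1561467476497545e-5",
    "8 1 0.2 0.00059306201680035314",
    "8 1 0.5 0.035661926719031811",
    "8 1 1 0.25413272802630464",
    "8 1 2 0.68999230561401488",
    "8 1 5 0.9842788374407428",
    "10 1 0.01 6.0154135606989065e-15",
    "10 1 0.1 1.4963727201194982e-6",
    "10 1 0.2 0.00019171701537406346",
    "10 1 0.5 0.02480196021494808",
    "10 1 1 0.2277612187846321",
    "10 1 2 0.67456099907914446",
    "10 1 5 0.98346223709929011",
    "12 1 0.01 1.8461132919498322e-17",
    "12 1 0.1 2.543673576968736e-7",
    "12 1 0.2 7.5546194046143766e-5",
    "12 1 0.5 0.018807168826654247",
    "12 1 1 0.21038923283447344",
    "12 1 2 0.663931729823587",
    "12 1 5 0.98289690512448109",
    "20 1 0.01 2.4064241588428877e-26",
    "20 1 0.1 1.2735536427020485e-9",
    "20 1 0.2 5.9988396871058328e-6",
    "20 1 0.5 0.0097173329918923472",
    "20 1 1 0.17640148866666326",
    "20 1 2 0.64181245047453774",
    "20 1 5 0.98171241895227121",
    "28 1 0.01 6.3040588390628923e-34",
    "28 1 0.1 3.5856659140252247e-11",
    "28 1 0.2 1.326948160827616e-6",
    "28 1 0.5 0.0069320997021811997",
    "28 1 1 0.16224713678335538",
    "28 1 2 0.63196705842793452",
    "28 1 5 0.98118145115976603",
    "30 1 0.01 1.1361632619291273e-35",
    "30 1 0.1 1.7429313882566775e-11",
    "30 1 0.2 9.9616767324931156e-7",
    "30 1 0.5 0.0065277458461358244",
    "30 1 1 0.1599172892502444",
    "30 1 2 0.63030417418520018",
    "30 1 5 0.98109152975557673",
    "3 2 0.5 0.57510074934630539",
    "3 3 0.5 0.22313016014842983",
    "6 3 0.5 0.42439475898463862",
    "10 4 0.2 0.19017108112854052",
    "30 15 0.1 0.07796612768741947")
  m <- do.call(rbind, lapply(strsplit(tab, " "), as.numeric))
  data.frame(i = m[, 1], j = m[, 2], T = m[, 3], g = m[, 4])
})

# canonical rooted-topology signature from a row of clade masks
mask_signature <- function(masks) paste(sort(masks), collapse = "-")

# clade-mask signature of a rooted 4-taxon topology given tip bit order
topo_signature <- function(newick, tip_order) {
  tr <- ape::read.tree(text = newick)
  k <- length(tip_order)
  bits <- 2^(match(tr$tip.label, tip_order) - 1)
  clades <- lapply(ape::prop.part(tr), function(ix) sum(bits[ix]))
  mask_signature(unlist(clades))
}
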