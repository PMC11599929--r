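# Shared fixtures, all generated in code.

# straight chain: soma + n axon nodes, unit steps along x
chain_tree <- function(n = 10, step = 1, type = 2L) {
  neuron_tree(data.frame(id = 1:(n + 1L), type = c(1L, rep(type, n)),
                         x = c(0, (1:n) * step), y = 0, z = 0,
                         radius = c(5, rep(0.5, n)),
                         parent = c(-1L, 1:n)))
}

# symmetric Y: 5 um stem up y, children 5 um at +/-45 deg from the stem axis
y_tree <- function() {
  s <- 5 * sqrt(2) / 2
  neuron_tree(data.frame(id = 1:4, type = c(1L, 2L, 2L, 2L),
                         x = c(0, 0, s, -s), y = c(0, 5, 5 + s, 5 + s), z = 0,
                         radius = 1, parent = c(-1L, 1L, 2L, 2L)))
}

# axon along x inside a block (soma just outside the rendered tube)
straight_axon_tree <- function(n = 50, step = 1, y = 32, z = 16, x0 = 7) {
  neuron_tree(data.frame(id = 1:(n + 1L), type = c(1L, rep(2L, n)),
                         x = c(x0, x0 + (1:n) * step), y = y, z = z,
                         radius = c(2, rep(1, n)), parent = c(-1L, 1:n)))
}

# neuron whose axon is g compact blobs joined by single long edges
blob_neuron <- function(g, seed, sep = 2000, spread = 80) {
  spec <- neuron_gen_spec(
    n_stems = 2,
    axon = list(tract_length = g * sep, n_arbors = g, arbor_sep = sep,
                arbor_spread = spread, arbor_branches = 15, tract_step = sep))
  synth_neuron(spec, seed)
}

# feature matrix whose pairwise correlation decays with soma distance:
# unit-phase rotation between two orthogonal feature directions
decay_features <- function(n = 100, p = 60, span = 4000, seed = 4) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(p * 2), p, 2)))
  u <- q[, 1] - mean(q[, 1]); v <- q[, 2] - mean(q[, 2])
  x <- seq(0, span, length.out = n)
  th <- x * pi / 2 / span
  list(features = outer(cos(th), u) + outer(sin(th), v),
       somas = cbind(x, 0, 0))
}

# small population with two well-shifted regions
two_region_population <- function(n = 30, rho = 0.3, seed = 9, shift = 2) {
  spec <- population_gen_spec(list(
    list(label = "A", center = c(500, 500, 500), extent = 200, n = n,
         rho = rho, shift = shift),
    list(label = "B", center = c(2000, 500, 500), extent = 200, n = n,
         rho = rho, shift = -shift)), n_features = 24)
  synth_population(spec, seed)
}

random_tree <- function(seed, depth = 4L) {
  synth_neuron(neuron_gen_spec(n_stems = sample(2:4, 1), bif_prob = 0.7,
                               max_depth = depth), seed)
}

cluster_purity <- function(truth, labels) {
  tb <- table(truth, labels)
  sum(apply(tb, 1L, max)) / sum(tb)
}
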