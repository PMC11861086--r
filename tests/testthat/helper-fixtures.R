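# Shared fixtures, built in code at test time.

tiny_cshape <- function() phantom_cshape(c(32L, 32L))
tiny_prostate <- function() phantom_prostate(c(32L, 32L))

tiny_kernel <- function() engine_kernel()

# an independent, straight-line transliteration of the five network layers,
# written against the published equations only (no shared code with the
# package's vectorized forward pass)
oracle_forward <- function(net, x_ptv, x_nt, x_oar) {
  sig <- function(x, a, b) 1 / (1 + exp(-a * (x - b)))
  w <- numeric(8)
  fi <- numeric(8)
  for (i in 1:8) {
    lab <- net$rule_table[i, ]
    mu_ptv <- sig(x_ptv, net$a["ptv", lab[["ptv"]]], net$b["ptv", lab[["ptv"]]])
    mu_nt <- sig(x_nt, net$a["nt", lab[["nt"]]], net$b["nt", lab[["nt"]]])
    mu_oar <- sig(x_oar, net$a["oar", lab[["oar"]]], net$b["oar", lab[["oar"]]])
    w[i] <- mu_ptv * mu_nt * mu_oar
    fi[i] <- net$consequents[i, 1] + net$consequents[i, 2] * x_ptv +
      net$consequents[i, 3] * x_nt + net$consequents[i, 4] * x_oar
  }
  sum(w / sum(w) * fi)
}

random_network <- function(seed, target = "wf_ptv") {
  set.seed(seed)
  net <- fis_network(target)
  net$a <- matrix(rnorm(6, 0, 3), 3, 2, dimnames = dimnames(net$a))
  net$b <- matrix(rnorm(6, 0, 0.3), 3, 2, dimnames = dimnames(net$b))
  net$consequents <- matrix(rnorm(32, 0, 0.5), 8, 4)
  net
}

# hand-built two-snapshot trajectory for dataset-construction checks
toy_trajectory <- function(id = "toy", pds = c(100, 20, 10)) {
  flat_dvh <- function(d) tibble::tibble(volume = seq(0, 100, 10), dose = d)
  snap <- function(t, doses, pd, wf) {
    tibble::tibble(
      phantom_id = id, t = t, channel = c("ptv", "oar", "nt"),
      pd = pd, wf = wf, mean_dose = doses,
      dvh = lapply(doses, flat_dvh)
    )
  }
  dplyr::bind_rows(
    snap(1L, c(90, 22, 12), pds, c(1, 1, 1)),
    snap(2L, c(95, 21, 11), c(110, 18, 9), c(1.5, 1.2, 0.8)),
    snap(3L, c(99, 20, 10), c(115, 17, 8), c(2.0, 1.5, 0.7))
  )
}
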