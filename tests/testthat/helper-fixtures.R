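## Shared fixtures: descriptive targets for the four constructs of the
## steady-state (D1370N-background) data set, and small oracle utilities.

## tau_burst, tau_interburst, tau_flicker (ms), n_flicker
construct_targets <- list(
  background     = c(2000, 5100, 10, 4.8),
  R117H          = c(67, 2800, 33, 1.2),
  E1124del       = c(100, 4800, 23, 2.1),
  R117H_E1124del = c(58, 3200, 50, 0.86))

target_model <- function(name, topology = "cs-o-cf") {
  tg <- construct_targets[[name]]
  rates_from_burst_stats(topology, tg[1], tg[2], tg[3], tg[4])
}

## Independent matrix exponential (full eigen, not the package's 2x2 path)
expm_oracle <- function(M, t) {
  e <- eigen(M)
  Re(e$vectors %*% diag(exp(e$values * t), nrow(M)) %*% solve(e$vectors))
}

## Corner-table convenience
table1_path <- system.file("extdata", "table1_d1370n.tsv", package = "burstkin")
table2_path <- system.file("extdata", "table2_e1371s.tsv", package = "burstkin")

corner_q <- function(tab, construct, transition, kind = "dwell_time") {
  r <- tab[tab$construct == construct & tab$transition == transition &
             tab$quantity_kind == kind, ]
  estimated_quantity(r$mean, r$sem, r$n,
                     kind = if (kind == "dwell_time") "dwell_time"
                     else if (kind == "rate") "rate" else "equilibrium_constant")
}
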