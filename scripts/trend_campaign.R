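#!/usr/bin/env Rscript
# Multi-state-point simulation campaign (hours on one CPU): gels at several
# volume fractions with longer quenches than the test suite uses, measuring
# mesh size, loop statistics, linking valence, linked fraction and both
# rheology routes. Writes a CSV of per-state-point observables and prints
# the fitted log-log slopes plus the predicted elasticity exponents.
#
# Usage: Rscript scripts/trend_campaign.R [--seed S] [--n N] [--tau T]
#                                         [--seeds K] [--out results/trends.csv]
# Defaults (N = 200, T = 1e4 tau_Br, 3 seeds) reproduce the scaled-down
# trend conditions; reduce --n/--tau for a faster pass.

suppressPackageStartupMessages(library(nanolink))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, n = 200L, tau = 1e4, seeds = 3L, out = "results/trends.csv")
i <- 1
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (!key %in% names(opt)) stop("unknown argument: ", args[i])
  opt[[key]] <- if (key == "out") args[i + 1] else as.numeric(args[i + 1])
  i <- i + 2
}
dir.create(dirname(opt$out), recursive = TRUE, showWarnings = FALSE)

rhos <- c(0.02, 0.06, 0.10)
rows <- list()
for (rho in rhos) {
  for (s in seq_len(opt$seeds)) {
    run_seed <- as.integer(opt$seed * 1000 + round(rho * 100) * 10 + s)
    nl_log_seed(sprintf("campaign rho=%.2f rep=%d", rho, s), run_seed)
    cfg <- init_configuration(opt$n, rho, seed = run_seed)
    tr <- run_langevin(cfg, force_field(), langevin_params(seed = run_seed + 1L),
                       simulation_protocol(equilibration = 50,
                                           production = opt$tau,
                                           frame_every = max(0.2, opt$tau / 5000),
                                           stress_every = 0.05),
                       tracer = tracer_bead(a = 2.5))
    fc <- tr$final
    b <- detect_bonds(fc)
    g <- build_bond_graph(fc, b)
    ls <- find_minimum_loops(g)
    cen <- link_census(ls, fc$box, config = fc)
    ms <- sample_mesh_size(fc, n_samples = 4000, seed = run_seed + 2L)
    bp <- branch_path_statistics(g)
    gk <- green_kubo_relaxation(tr$stress, max_lag_frac = 0.01)
    gk_fit <- tryCatch(
      fit_stretched_exponential(list(t = gk$t[gk$t >= 0.5], g = gk$g[gk$t >= 0.5])),
      error = function(e) list(a = NA_real_, tau = NA_real_, b = NA_real_))
    msd <- compute_msd(tr$tracer_track, dt = max(0.2, opt$tau / 5000), a = 2.5)
    gser_plat <- tryCatch({
      sp2 <- gser_moduli(msd)
      max(sp2$g1[!sp2$masked])
    }, error = function(e) NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      rho = rho, rep = s, bonded = b$bonded_fraction,
      xi = mean(ms$xi[!ms$capped]),
      lmin = if (ls$n_minloop) mean(ls$l_min) else NA,
      n_minloop = ls$n_minloop,
      lambda = bp$mean_lambda,
      total_linking = cen$total_linking,
      z = cen$linking_valence,
      linked_fraction = cen$linked_fraction,
      percolates = cen$percolates,
      gk_plateau = gk_fit$a, gk_tau = gk_fit$tau, gk_b = gk_fit$b,
      gser_plateau = gser_plat)
    utils::write.csv(do.call(rbind, rows), opt$out, row.names = FALSE)
  }
}
tab <- do.call(rbind, rows)
print(tab)

agg <- stats::aggregate(tab[c("xi", "n_minloop", "z", "lmin", "gk_plateau")],
                        by = tab["rho"], FUN = mean, na.rm = TRUE)
cat("\nper-density means:\n"); print(agg)
slope <- function(y) {
  ok <- is.finite(y) & y > 0
  if (sum(ok) < 3) return(c(NA, NA))
  f <- fit_power_law(agg$rho[ok], y[ok])
  c(f$segments$all$slope, f$segments$all$slope_se)
}
sx <- slope(agg$xi); sn <- slope(agg$n_minloop); sz <- slope(agg$z)
sl <- slope(agg$lmin); sg <- slope(agg$gk_plateau)
cat(sprintf("\nslopes: xi %.2f+/-%.2f  N_minloop %.2f+/-%.2f  Z %.2f+/-%.2f  l_min %.2f+/-%.2f  G'_p %.2f+/-%.2f\n",
            sx[1], sx[2], sn[1], sn[2], sz[1], sz[2], sl[1], sl[2], sg[1], sg[2]))
if (all(is.finite(c(sn[1], sz[1], sx[1], sl[1])))) {
  print(predict_scaling_exponents(nminloop_slope = sn, z_slope = sz,
                                  xi_slope = sx, lmin_slope = sl))
}
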