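#!/usr/bin/env Rscript
# Step 4 — calibration of the R/S Hurst estimator against exact fGn.
#
# The fGn sampler provides series with known H; the table below reports
# the mean estimate (50 seeded series per H, N = 1024, ten log-spaced
# windows 10..512) for the raw log-log fit and the Anis-Lloyd-corrected
# fit, plus the 100-series white-noise anchor. The corrected estimator
# removes the finite-sample inflation (visible at low H) at the cost of
# amplifying the intrinsic downward attenuation of R/S at high H.

library(boldhurst)

N <- 1024L
sc <- default_scales(N)
H_true <- c(0.3, 0.5, 0.7, 0.9)
tab <- t(sapply(H_true, function(H) {
  X <- simulate_fgn(H, N, n_series = 50, seed = 300 + round(100 * H))
  rs <- boldhurst:::rs_curve_matrix(X, sc)
  c(H_true = H,
    mean_H_raw = mean(boldhurst:::fit_hurst_matrix(rs$mean_rs, sc, FALSE)$H),
    mean_H_corrected = mean(boldhurst:::fit_hurst_matrix(rs$mean_rs, sc, TRUE)$H))
}))
tab <- as.data.frame(tab)
tab$bias_raw <- tab$mean_H_raw - tab$H_true
tab$bias_corrected <- tab$mean_H_corrected - tab$H_true
print(round(tab, 4))
write.csv(tab, "results/hurst_recovery.csv", row.names = FALSE)

set.seed(41)
W <- matrix(rnorm(N * 100L), N, 100L)
rs <- boldhurst:::rs_curve_matrix(W, sc)
anchor <- mean(boldhurst:::fit_hurst_matrix(rs$mean_rs, sc, TRUE)$H)
cat(sprintf("white-noise anchor (corrected, 100 series): mean H = %.4f\n", anchor))
cat("monotone in true H:",
    all(diff(tab$mean_H_raw) > 0) && all(diff(tab$mean_H_corrected) > 0), "\n")
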