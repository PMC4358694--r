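#!/usr/bin/env Rscript
# How many specimens does a given strength of allometry need? Fit the
# hyperbolic models y = m/|x - b| and y = m/|x - b| + c to the (slope,
# minimum n) points from the random-scheme sweep, compare them with AIC and
# Akaike weights, and repeat the fit on the published alligator slope/min-n
# pairs. The asymptote b is expected at (just below) the isometric slope 1.
suppressPackageStartupMessages(library(allopower))

minn <- utils::read.csv("results/min_sample_sizes.csv")
rand <- minn[minn$scheme == "random" & minn$true_category != "isometric", ]
pts <- scaling_points(rand$slope, rand$min_n, rand$censored)
fits <- list(fit_hyperbola(pts, "eq1"), fit_hyperbola(pts, "eq2"))
report_hyperbola(fits, "results/scaling_law_synthetic.csv")
cat(sprintf("synthetic sweep: b = %.4f (eq1), %d points, eq1 weight %.3f\n",
            fits[[1]]$par[["b"]], fits[[1]]$n_points,
            compare_models(fits)$weight[1]))

pub <- alligator_published_results()
pub_pts <- scaling_points(pub$slope, pub$min_n_random, pub$cens_random)
pub_fits <- list(fit_hyperbola(pub_pts, "eq1"), fit_hyperbola(pub_pts, "eq2"))
report_hyperbola(pub_fits, "results/scaling_law_published.csv")
cat(sprintf("published pairs: b = %.4f, 95%% CI (%.4f, %.4f)\n",
            pub_fits[[1]]$par[["b"]], pub_fits[[1]]$ci["b", "low"],
            pub_fits[[1]]$ci["b", "high"]))
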