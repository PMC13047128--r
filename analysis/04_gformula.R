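#!/usr/bin/env Rscript
# Stage 4: joint mediation via the mediational g-formula.
#
# Two-way decomposition (total / direct / joint indirect / residual xi)
# and path-specific decomposition (depression, then cognition) of the
# effect of a sustained high-vs-low RBDSQ contrast on final-visit ADL,
# with subject-level bootstrap percentile intervals.

library(longmed)

panel <- load_cohort("results/cohort.csv")
spec <- gformula_spec(n_mc = 20000, n_boot = 200, seed = 20260320)

bs <- gformula_bootstrap(panel, spec, n_mc_boot = 5000)
est <- bs$estimate

tab5 <- merge(
  data.frame(component = bs$ci$component, estimate = bs$ci$estimate,
             ci_low = bs$ci$ci_low, ci_high = bs$ci$ci_high),
  data.frame(component = c("de", "ie_joint", "ie_gds15", "ie_moca"),
             share_pct = c(est$de_share, est$ie_share,
                           est$per_mediator_share[["gds15"]],
                           est$per_mediator_share[["moca"]])),
  by = "component", all.x = TRUE)
utils::write.csv(tab5, "results/table5_decomposition.csv",
                 row.names = FALSE)

cat("Sustained exposure contrast (per-visit RBDSQ):\n")
cat("  x_high =", paste(bs$contrast$x_high, collapse = " "),
    " vs x_low =", paste(bs$contrast$x_low, collapse = " "), "\n")
print(bs)
cat("\nInterpretation: moving from the low to the high sustained RBDSQ\n",
    "regime raises final-visit ADL limitation by the total effect in\n",
    "points; the joint indirect share flows through depression and\n",
    "cognition, with depression the larger contributor. xi is the\n",
    "residual between the unmediated anchor total effect and the\n",
    "mediational model's decomposition; the identity\n",
    "te = de + ie_joint + xi is exact by construction:",
    est$te - (est$de + est$ie_joint + est$xi), "\n")
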