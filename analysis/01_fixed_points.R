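#!/usr/bin/env Rscript
# Fixed-point structure of the promoter model at the reference parameter
# profile: the five coexisting regulatory states (H3K27me3 (a), bivalent
# (b), H3K4me3 (c), unmodified low-methylation (d), unmodified
# high-methylation (e)) and the eight unstable solutions between them;
# plus the same analysis for the G1-like gene (eps_BS = 5.5) and under
# elevated de novo DNMT activity (D_novo_0 = 0.3), where the H3K27me3 and
# the low-methylation unmodified state vanish.

library(epiprotect)

dir.create("results", showWarnings = FALSE)

p <- epi_params()
fp <- find_fixed_points(p)
cat("Reference profile A (F_TF = 1, eps_BS = 5.0, D_novo_0 = 0.1):\n")
cat(sprintf("  %d fixed points: %d stable (%s), %d unstable\n",
            nrow(fp), sum(fp$stable),
            paste(sort(fp$label[fp$stable]), collapse = ", "),
            sum(!fp$stable)))
fp$x4 <- nonlinear_scale(pmax(fp$m4, 1e-9), p$m4_max)
fp$x27 <- nonlinear_scale(pmax(fp$m27, 1e-9), p$m27_max)
write.table(format(fp, digits = 6), "results/fixed_points_reference.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

g1 <- epi_params(eps_BS = 5.5)
fp_g1 <- find_fixed_points(g1)
st <- fp_g1[fp_g1$stable, ]
Ta <- st$T[st$label == "a"][1]
Tb <- st$T[st$label == "b"][1]
Tc <- st$T[st$label == "c"][1]
cat("\nG1-like gene (eps_BS = 5.5):\n")
cat(sprintf("  stable states: %s\n", paste(sort(st$label), collapse = ", ")))
cat(sprintf("  T(H3K4me3) - T(bivalent)  = %.3f  (strong down-step c -> b)\n",
            Tc - Tb))
cat(sprintf("  T(bivalent) - T(H3K27me3) = %.3f  (weak up-step a -> b)\n",
            Tb - Ta))
write.table(format(fp_g1, digits = 6), "results/fixed_points_eps55.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

hi <- epi_params(D_novo_0 = 0.3)
fp_hi <- find_fixed_points(hi)
cat("\nElevated de novo methylation (D_novo_0 = 0.3):\n")
cat(sprintf("  stable states: %s  (a and d have vanished)\n",
            paste(sort(fp_hi$label[fp_hi$stable]), collapse = ", ")))
write.table(format(fp_hi, digits = 6), "results/fixed_points_dnovo03.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
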