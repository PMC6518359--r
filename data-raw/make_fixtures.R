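# Generates the synthetic dosimetry fixtures shipped under inst/extdata.
#
# These stand in for proprietary sphere-model and adult-phantom S-factor
# tables, which cannot be redistributed; every file they produce is
# labelled synthetic and no numeric agreement with any dosimetry program
# is claimed.  Run from the package root:
#   Rscript data-raw/make_fixtures.R

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)

# --- Cu-64 unit-density-sphere S-values ------------------------------------
# A pure power law S(m) = a * m^b anchored near the Cu-64 equilibrium dose
# constant for locally absorbed emissions (~70 mGy*g/(MBq*h), so ~70
# mGy/(MBq*h) for a 1 g sphere); the exponent is slightly shallower than -1
# because small spheres lose a growing fraction of the emitted energy.
a <- 70
b <- -0.95
mass_g <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10)
svals <- data.frame(mass_g = mass_g,
                    s_mGy_per_MBq_h = signif(a * mass_g^b, 8))
write.csv(svals, "inst/extdata/svalues_cu64_sphere_synthetic.csv",
          row.names = FALSE, quote = FALSE)

# --- Adult-phantom-like organ S-factor matrix ------------------------------
# Self-dose k/m_target with a flat 3% cross-organ term, guaranteeing
# diagonal dominance per target row.  Tissue weighting factors are an
# ICRP-like subset renormalized to sum to exactly 1 over these organs.
organs <- c("liver", "kidneys", "spleen", "lungs", "brain", "stomach",
            "intestines")
human_mass <- c(liver = 1800, kidneys = 310, spleen = 150, lungs = 1200,
                brain = 1400, stomach = 400, intestines = 1000)
w_raw <- c(liver = 0.04, kidneys = 0.02, spleen = 0.01, lungs = 0.12,
           brain = 0.01, stomach = 0.12, intestines = 0.12)
w <- w_raw / sum(w_raw)
k <- 70  # mGy*g/(MBq*h)
S <- outer(organs, organs, function(t, s) {
  ifelse(t == s, 1, 0.03) * k / human_mass[t]
})
smat <- data.frame(target = organs, round(S, 8),
                   mass_g = human_mass[organs],
                   weight = round(w[organs], 10))
names(smat)[2:(1 + length(organs))] <- organs
# force exact unit sum after rounding
smat$weight[1] <- smat$weight[1] + (1 - sum(smat$weight))
write.csv(smat, "inst/extdata/smatrix_synthetic.csv",
          row.names = FALSE, quote = FALSE)

# --- Organ masses for residence-time scaling --------------------------------
mouse <- data.frame(
  region = c("tumor", "liver", "kidneys", "spleen", "lungs", "brain",
             "stomach", "intestines", "total_body"),
  mass_g = c(0.2, 1.3, 0.4, 0.1, 0.15, 0.4, 0.5, 2.0, 25)
)
human <- data.frame(
  region = c("liver", "kidneys", "spleen", "lungs", "brain", "stomach",
             "intestines", "total_body"),
  mass_g = c(1800, 310, 150, 1200, 1400, 400, 1000, 73000)
)
write.csv(mouse, "inst/extdata/mouse_organ_masses_synthetic.csv",
          row.names = FALSE, quote = FALSE)
write.csv(human, "inst/extdata/human_organ_masses_synthetic.csv",
          row.names = FALSE, quote = FALSE)
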