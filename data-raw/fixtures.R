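# Regenerates the packaged text fixtures under inst/extdata/.
# Run from the package root: Rscript data-raw/fixtures.R

# Published GEE utility regression (coefficients as printed, long format).
util <- c(constant = 0.880, d_moderate = -0.078, d_marked = -0.122,
          d_severe = -0.168, bone_pain = -0.098, ssc = 0.018,
          female = -0.049, age_at_init = -0.002,
          mean_female = 0.691, mean_age = 53.9)
write.csv(data.frame(term = names(util), value = unname(util)),
          "inst/extdata/table1_utility.csv", row.names = FALSE, quote = FALSE)

# Published ordered-logit transition regression.
trans <- c(prev_2 = 1.305, prev_3 = 0.840, prev_4 = 2.581, prev_5 = 1.253,
           prev_6 = 4.504, prev_7 = 3.617, prev_8 = 4.213, prev_9 = 6.072,
           years_2 = 0.293, years_3plus = 0.315,
           d_moderate = -0.150, d_marked = 0.873, d_severe = 1.349,
           not_splenectomized = -1.089,
           cutpoint_1 = 0.740, cutpoint_2 = 1.662, cutpoint_3 = 1.727,
           cutpoint_4 = 5.054, cutpoint_5 = 5.835, cutpoint_6 = 6.577,
           cutpoint_7 = 8.808, cutpoint_8 = 9.066)
write.csv(data.frame(term = names(trans), value = unname(trans)),
          "inst/extdata/table2_transitions.csv", row.names = FALSE, quote = FALSE)

# Synthetic Gompertz-Makeham general-population life table approximating
# UK period mortality: hazard h(x) = A + B exp(C x). Parameters chosen for
# a life expectancy at birth of about 81 years. SYNTHETIC: stands in for a
# Human Mortality Database export with the same (age, qx) schema.
A <- 2.2e-4; B <- 1.1e-5; C <- 0.105
age <- 0:110
H <- A + (B / C) * (exp(C * (age + 1)) - exp(C * age))  # integrated hazard over [x, x+1)
qx <- 1 - exp(-H)
qx[length(qx)] <- 1
write.csv(data.frame(age = age, qx = sprintf("%.6f", qx)),
          "inst/extdata/lifetable_uk_synthetic.csv", row.names = FALSE, quote = FALSE)
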