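# shared fixtures: everything is generated in code at test time

ref_params <- function() default_params()

small_cohort_data <- function(n = 20, seed = 7, params = default_params()) {
  generate_cohort(cohort_design(n_patients = n), params, seed = seed)
}

# a single hand-built subject record
manual_record <- function(grades, doses = rep(3000, length(grades)),
                          times = seq_along(grades)) {
  list(id = 1L, age = 62, sex = "female", entity = "breast", mono = TRUE,
       adherence = ">100%",
       cycles = data.frame(cycle = seq_along(grades), time = times,
                           dose = doses, grade = grades))
}

# published bootstrap 95% confidence intervals used as recovery tolerances
published_ci <- function() {
  rbind(alpha1 = c(1.38, 2.51), b2 = c(-2.23, -1.45), b3 = c(-2.73, -1.57),
        met = c(0.896, 1.430), theta_dose = c(4.05e-4, 1.48e-3),
        omega_alpha = c(0.0112, 1.65), omega_met = c(0.310, 0.842))
}
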