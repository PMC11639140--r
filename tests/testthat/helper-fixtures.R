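# Shared design fixtures, built in code (the OA builder is deterministic).
oa_fx <- build_orthogonal_array()
tto_design_fx <- map_to_states(oa_fx, "TTO")
dce_states_fx <- map_to_states(oa_fx, "DCE")
dce_pairs_fx <- build_dce_pairs(dce_states_fx)

dims_fx <- c("WE", "LO", "DA", "LE", "PA", "TI", "AN", "DE")
sym_fx <- c("WE", "LO", "PA", "TI")

# small simulated datasets reused across files
truth_fx <- make_truth("paper-like")
tto_small_fx <- simulate_tto(truth_fx, tto_design_fx, n_respondents = 40, seed = 101)
dce_small_fx <- simulate_dce(truth_fx, dce_pairs_fx, n_respondents = 80, seed = 102)

# a random admissible coefficient vector for a spec (uniform inside bounds)
rand_coefs <- function(spec, seed) {
  set.seed(seed)
  pt <- model_bounds(spec)
  val <- stats::setNames(pt$value, pt$name)
  free <- !pt$fixed
  lo <- pmax(pt$lower[free], 0)
  hi <- ifelse(is.finite(pt$upper[free]), pt$upper[free], 0.6)
  val[pt$name[free]] <- lo + stats::runif(sum(free)) * (hi - lo)
  if ("theta" %in% names(val)) val["theta"] <- runif(1, 0.5, 1.5)
  if ("alpha_sigma" %in% names(val)) val["alpha_sigma"] <- runif(1, 0.15, 0.5)
  if ("beta_sigma" %in% names(val)) val["beta_sigma"] <- runif(1, 0, 0.3)
  if ("sigma" %in% names(val)) val["sigma"] <- runif(1, 0.15, 0.5)
  if ("alpha_tto" %in% names(val)) val["alpha_tto"] <- runif(1, 0, 0.2)
  if ("alpha_dce" %in% names(val)) val["alpha_dce"] <- rnorm(1, 0, 0.3)
  val
}
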