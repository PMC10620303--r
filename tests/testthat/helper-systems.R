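# Shared generators and lazily cached expensive objects.

# deterministic random parameter set (not necessarily admissible)
random_params <- function(seed, D_u = 1, D_v = 20) {
  set.seed(seed)
  rates <- lapply(stats::setNames(nm = rate_keys()), function(k)
    c(alpha = runif(1, 0.01, 0.1), beta = runif(1, 0.5, 2),
      gamma = runif(1, 1, 10)))
  kappa <- stats::setNames(runif(16, 0.1, 10), kappa_keys())
  mg_params(rates, kappa, D_u, D_v)
}

# unit-rate parameter set for key bookkeeping
unit_params <- function() {
  mg_params(lapply(stats::setNames(nm = rate_keys()), function(k)
    c(alpha = 1, beta = 1, gamma = 1)),
    stats::setNames(rep(1, 16), kappa_keys()), D_u = 1, D_v = 20)
}

# a pure-diffusion (zero reaction) two-species system, for mass tests
diffusion_only_system <- function(D_u = 1, D_v = 20) {
  mgturing:::new_reaction_system(
    species = c("ub", "vb"), tf = c("u", "v"), allele = c("A", "A"),
    alpha = c(0, 0), beta = c(0, 0), gamma = c(0, 0),
    KU = matrix(0, 2, 2), KV = matrix(0, 2, 2),
    kappa_keys = matrix("", 2, 2), D_u = D_u, D_v = D_v,
    genotype = mg_genotype("AA", "AA"))
}

# symmetric-fixture parent description (rates + cis kappa)
symmetric_parent <- function(params = mg_fixture("symmetric")) {
  list(rates = list(u = params$rates$u_A, v = params$rates$v_A),
       kappa = c(uu = unname(params$kappa["uu_AA"]),
                 uv = unname(params$kappa["uv_AA"]),
                 vu = unname(params$kappa["vu_AA"]),
                 vv = unname(params$kappa["vv_AA"])))
}

# lazily cached simulation results shared across test files
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# patterned F1 field of the general fixture on a modest grid
general_f1_field <- function() {
  cached("general_f1", {
    p <- mg_fixture("general")
    sys <- build_system(p, "U:AB,V:AB")
    ss <- find_steady_state(sys)
    cfg <- sim_config(nx = 64, ny = 64, t_max = 2000, rng_seed = 1)
    list(params = p, system = sys, ss = ss, config = cfg,
         field = run_to_steady(sys, config = cfg, steady_state = ss,
                               stop_when = "saturated"))
  })
}
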