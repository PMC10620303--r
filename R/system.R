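# ReactionSystem: a concrete n-species (n in 2..4) reaction-diffusion system
# for one genotype. Reaction term of species i is
#   alpha_i - beta_i x_i + gamma_i * (U_i / (1 + U_i + V_i))^2
# with U_i = (KU x)_i (activator binding) and V_i = (KV x)_i (inhibitor
# binding), both nonnegative linear combinations of concentrations.
new_reaction_system <- function(species, tf, allele, alpha, beta, gamma,
                                KU, KV, kappa_keys, D_u, D_v, genotype,
                                mult = rep(1, length(species))) {
  structure(list(
    species = species, tf = tf, allele = allele,
    alpha = alpha, beta = beta, gamma = gamma, mult = mult,
    KU = KU, KV = KV, kappa_keys = kappa_keys,
    D_u = D_u, D_v = D_v, genotype = genotype), class = "reaction_system")
}

#' Number of species of a reaction system
#' @param system A `reaction_system`.
#' @return Integer, 2 to 4.
#' @export
n_species <- function(system) length(system$species)

# per-species diffusion coefficients at inhibitor/activator ratio d
diffusion_coefs <- function(system, d = system$D_v / system$D_u) {
  ifelse(system$tf == "u", system$D_u, d * system$D_u)
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("reaction_system: %d species (%s) for genotype %s\n",
              n_species(x), paste(x$species, collapse = ", "),
              format(x$genotype)))
  tab <- data.frame(tf = x$tf, allele = x$allele, alpha = x$alpha,
                    beta = x$beta, gamma = x$gamma, row.names = x$species)
  print(tab)
  invisible(x)
}

#' Build the uncontracted four-species diploid system for a genotype
#'
#' Instantiates the four-variable reaction-diffusion system for one diploid
#' genotype: species ordered `(u, v, uh, vh)` where `u`/`uh` are the two
#' activator gene products (haplotypes 1 and 2 of locus U) and `v`/`vh` the
#' two inhibitor gene products. Rate constants carry the allele superscript
#' of their own species; binding constants carry the (regulated allele,
#' binding allele) pair, so the doubly heterozygous genotype references all
#' 16 and a doubly homozygous genotype only the 4 same-allele entries.
#'
#' @param params A `mg_params` multigenerational parameter set.
#' @param genotype A `mg_genotype` or genotype string such as `"U:AB,V:AB"`.
#' @return A 4-species `reaction_system`.
#' @seealso [contract_system()] to merge species at homozygous loci,
#'   [build_system()] for the contracted system in one call.
#' @export
build_diploid_system <- function(params, genotype) {
  genotype <- parse_genotype(genotype)
  params <- validate_params(params)
  asg <- assign_parameters(genotype, params)
  species <- c("u", "v", "uh", "vh")
  tf <- c("u", "v", "u", "v")
  rates <- do.call(rbind, lapply(asg$rates, unlist))
  K <- asg$kappa
  is_u <- matrix(rep(tf == "u", each = 4), 4, 4)
  KU <- K * is_u
  KV <- K * !is_u
  dimnames(KU) <- dimnames(KV) <- dimnames(K)
  new_reaction_system(
    species = species, tf = tf,
    allele = c(locus_alleles(genotype$U)[1], locus_alleles(genotype$V)[1],
               locus_alleles(genotype$U)[2], locus_alleles(genotype$V)[2]),
    alpha = rates[, "alpha"], beta = rates[, "beta"], gamma = rates[, "gamma"],
    KU = KU, KV = KV, kappa_keys = asg$kappa_keys,
    D_u = params$D_u, D_v = params$D_v, genotype = genotype)
}

#' Contract a diploid system at its homozygous loci
#'
#' At a homozygous locus the two gene products obey identical equations, so
#' the pair can be replaced by its sum (`ub = u + uh` and/or `vb = v + vh`).
#' In the contracted equations the zeroth-order rate constants (`alpha`,
#' `gamma`) appear doubled while the first-order `beta` is unchanged, and
#' the two identical binding columns collapse into one. Heterozygous loci
#' are left split; the doubly heterozygous system is returned unchanged.
#' Contraction keys off the genotype only: allele-identical parameters at a
#' heterozygous locus do not trigger contraction.
#'
#' @param system A 4-species `reaction_system` from [build_diploid_system()].
#' @return A `reaction_system` with 2, 3, or 4 species.
#' @export
contract_system <- function(system) {
  stopifnot(inherits(system, "reaction_system"))
  if (n_species(system) != 4)
    stop("contract_system expects the uncontracted 4-species system",
         call. = FALSE)
  g <- system$genotype
  merge_u <- is_homozygous(g$U)
  merge_v <- is_homozygous(g$V)
  if (!merge_u && !merge_v) return(system)

  keep <- c(TRUE, TRUE, !merge_u, !merge_v)  # drop second copy when merged
  idx <- which(keep)
  lab <- system$species[idx]
  if (merge_u) lab[lab == "u"] <- "ub"
  if (merge_v) lab[lab == "v"] <- "vb"

  # column collapse: the merged pair's columns are identical (same binding
  # allele), keep one; row scale: zeroth-order terms doubled
  collapse_cols <- function(M) {
    stopifnot(!merge_u || isTRUE(all.equal(M[, 1], M[, 3])),
              !merge_v || isTRUE(all.equal(M[, 2], M[, 4])))
    M[idx, idx, drop = FALSE]
  }
  mult <- ifelse(lab %in% c("ub", "vb"), 2, 1)
  new_reaction_system(
    species = lab, tf = system$tf[idx], allele = system$allele[idx],
    alpha = mult * system$alpha[idx], beta = system$beta[idx],
    gamma = mult * system$gamma[idx],
    KU = collapse_cols(system$KU), KV = collapse_cols(system$KV),
    kappa_keys = system$kappa_keys[idx, idx, drop = FALSE],
    D_u = system$D_u, D_v = system$D_v, genotype = g, mult = mult)
}

#' Build the contracted reaction system for a genotype
#'
#' Convenience wrapper: [build_diploid_system()] followed (by default) by
#' [contract_system()].
#'
#' @inheritParams build_diploid_system
#' @param contract Merge species at homozygous loci (default `TRUE`).
#' @return A `reaction_system`.
#' @export
build_system <- function(params, genotype, contract = TRUE) {
  sys <- build_diploid_system(params, genotype)
  if (contract) contract_system(sys) else sys
}

# Hill saturation H_i = U_i/(1+U_i+V_i) and intermediates, vectorized over
# states given as rows of a matrix
hill_parts <- function(system, X) {
  U <- X %*% t(system$KU)
  V <- X %*% t(system$KV)
  list(U = U, V = V, H = U / (1 + U + V))
}

#' Evaluate the reaction terms of a system
#'
#' Returns the reaction part of `d(state)/dt` (no diffusion): component `i`
#' is `alpha_i - beta_i x_i + gamma_i (U_i/(1+U_i+V_i))^2`.
#'
#' @param system A `reaction_system`.
#' @param state Numeric vector of concentrations, componentwise `>= 0`,
#'   length equal to [n_species()].
#' @return Numeric vector of reaction rates.
#' @export
eval_reaction_terms <- function(system, state) {
  n <- n_species(system)
  if (length(state) != n)
    stop("state has length ", length(state), ", system has ", n, " species",
         call. = FALSE)
  if (any(state < 0))
    stop("negative concentration in state", call. = FALSE)
  as.vector(reaction_rates(system, matrix(state, 1)))
}

# matrix form: rows of X are states; returns matrix of rates (same shape)
reaction_rates <- function(system, X) {
  hp <- hill_parts(system, X)
  sweep(hp$H^2, 2, system$gamma, `*`) +
    rep(system$alpha, each = nrow(X)) -
    sweep(X, 2, system$beta, `*`)
}

#' Analytic Jacobian of the reaction terms
#'
#' Closed-form partial derivatives of the reaction terms with respect to the
#' species concentrations:
#' `J_ij = -beta_i delta_ij + 2 gamma_i U_i (KU_ij (1 + V_i) - U_i KV_ij) /
#' (1 + U_i + V_i)^3`. For the 4-species system the `(u, v, uh, vh)`
#' ordering exposes the 2x2 haplotype block structure.
#'
#' @param system A `reaction_system`.
#' @param state Concentration vector (typically a steady state, but the
#'   expression is valid at any nonnegative state).
#' @return A square numeric matrix with species dimnames.
#' @export
reaction_jacobian <- function(system, state) {
  n <- n_species(system)
  stopifnot(length(state) == n)
  hp <- hill_parts(system, matrix(state, 1))
  U <- as.vector(hp$U); V <- as.vector(hp$V)
  pref <- 2 * system$gamma * U / (1 + U + V)^3
  J <- pref * (system$KU * (1 + V) - U * system$KV)
  J <- J - diag(system$beta, n)
  dimnames(J) <- list(system$species, system$species)
  J
}
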