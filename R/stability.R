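# Linear stability machinery: steady states of the reaction terms, the
# dispersion relation of the linearized reaction-diffusion operator, and the
# critical inhibitor-to-activator diffusion ratio d* at the Turing
# bifurcation.

# strict stability margin: "stable" means max Re(eigenvalue) < -STAB_MARGIN
STAB_MARGIN <- 1e-9

max_re_eig <- function(M) max(Re(eigen(M, only.values = TRUE)$values))

# damped Newton on the reaction terms with the analytic Jacobian;
# returns the root or NULL
newton_root <- function(system, x0, tol = 1e-10, maxit = 200) {
  x <- x0
  for (i in seq_len(maxit)) {
    fx <- as.vector(reaction_rates(system, matrix(x, 1)))
    if (max(abs(fx)) < tol) return(x)
    J <- reaction_jacobian(system, pmax(x, 0))
    dx <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    step <- 1
    repeat {
      xn <- x + step * dx
      if (all(xn > 0) && all(is.finite(xn))) break
      step <- step / 2
      if (step < 1e-12) return(NULL)
    }
    x <- xn
  }
  fx <- as.vector(reaction_rates(system, matrix(x, 1)))
  if (max(abs(fx)) < tol * 10) x else NULL
}

#' Find the spatially homogeneous steady state of a reaction system
#'
#' Solves the reaction terms for a root by damped Newton iteration from
#' multiple starting points (log-spaced multiples of the low-state scale
#' `alpha/beta`, spanning `[1e-3, 1e3]`). Distinct converged roots flag the
#' steady state as non-unique; the model can have three steady states for
#' some parameter sets, and downstream analyses are restricted to the
#' unique-root case.
#'
#' @param system A `reaction_system`.
#' @param n_starts Number of Newton starting points (default 32).
#' @param tol Residual tolerance `max |reaction terms|` (default 1e-10).
#' @return A list of class `steady_state`: `concentrations` (the root with
#'   the smallest activator total, named by species), `residual`, `unique`
#'   (logical), and `roots` (all distinct roots found).
#' @export
find_steady_state <- function(system, n_starts = 32, tol = 1e-10) {
  base <- system$alpha / system$beta
  scales <- 10^seq(-3, 3, length.out = n_starts)
  roots <- list()
  for (s in scales) {
    r <- newton_root(system, base * s, tol = tol)
    if (is.null(r)) {
      # fallback: damped fixed-point warm-up x <- (alpha + gamma H^2)/beta
      # pulls a stray start into a Newton basin (it contracts toward stable
      # roots, so it is used only when raw Newton fails)
      x0 <- base * s
      for (i in 1:40) {
        H <- hill_parts(system, matrix(x0, 1))$H
        x0 <- 0.5 * x0 + 0.5 * (system$alpha + system$gamma *
                                  as.vector(H)^2) / system$beta
      }
      r <- newton_root(system, x0, tol = tol)
    }
    if (is.null(r)) next
    dup <- any(vapply(roots, function(q)
      max(abs(q - r) / pmax(abs(q), 1e-12)) < 1e-6, TRUE))
    if (!dup) roots[[length(roots) + 1]] <- r
  }
  if (!length(roots))
    stop("no steady state found from any start (", n_starts, " starts)",
         call. = FALSE)
  ord <- order(vapply(roots, function(r) sum(r[system$tf == "u"]), 0))
  roots <- roots[ord]
  x <- setNames(roots[[1]], system$species)
  structure(list(
    concentrations = x,
    residual = max(abs(eval_reaction_terms(system, x))),
    unique = length(roots) == 1L,
    roots = roots), class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("steady state:", paste(sprintf("%s=%.5g", names(x$concentrations),
                                     x$concentrations), collapse = ", "), "\n")
  cat(sprintf("residual %.2e, %s\n", x$residual,
              if (x$unique) "unique" else
                sprintf("NON-unique (%d roots)", length(x$roots))))
  invisible(x)
}

# growth rate of spatial mode with squared wavenumber k2, at diffusion ratio d
growth_at <- function(J, Dvec, k2) max_re_eig(J - diag(k2 * Dvec, nrow(J)))

#' Dispersion relation of the linearized reaction-diffusion system
#'
#' For each spatial frequency `k`, the growth rate is the maximum real part
#' of the eigenvalues of `J - k^2 diag(D)`, where `J` is the reaction
#' Jacobian at the steady state and `D` assigns `D_u` to activator species
#' and `d * D_u` to inhibitor species.
#'
#' @param system A `reaction_system`.
#' @param steady_state A `steady_state` (or bare concentration vector).
#' @param d Inhibitor-to-activator diffusion ratio `D_v/D_u` (default from
#'   the system's own coefficients).
#' @param k Vector of spatial frequencies (1/length).
#' @return A data frame of class `dispersion_curve` with columns `k` and
#'   `growth_rate`.
#' @export
dispersion <- function(system, steady_state, d = system$D_v / system$D_u,
                       k = default_k_grid(system)) {
  x <- ss_vector(steady_state)
  J <- reaction_jacobian(system, x)
  if (max_re_eig(J) >= -STAB_MARGIN)
    stop("reaction Jacobian is not stable at k = 0; Turing analysis ",
         "requires linear stability of the reaction terms", call. = FALSE)
  Dvec <- diffusion_coefs(system, d)
  gr <- vapply(k, function(ki) growth_at(J, Dvec, ki^2), 0)
  structure(data.frame(k = k, growth_rate = gr),
            class = c("dispersion_curve", "data.frame"))
}

ss_vector <- function(steady_state) {
  if (inherits(steady_state, "steady_state")) steady_state$concentrations
  else steady_state
}

# default k grid spanning the reaction/diffusion balance scale
default_k_grid <- function(system, n = 100) {
  kc <- sqrt(max(system$beta) / system$D_u)
  c(0, 10^seq(log10(kc) - 2, log10(kc) + 1.5, length.out = n - 1))
}

# sup over k > 0 of the growth rate: coarse log-spaced scan of k^2 followed
# by golden-section (optimize) refinement around the best point
max_growth <- function(J, Dvec, beta_scale, D_scale) {
  k2c <- beta_scale / D_scale
  grid <- 10^seq(log10(k2c) - 4, log10(k2c) + 3, length.out = 60)
  g <- vapply(grid, function(k2) growth_at(J, Dvec, k2), 0)
  i <- which.max(g)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(k2) growth_at(J, Dvec, k2),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  if (opt$objective >= g[i]) list(value = opt$objective, k2 = opt$maximum)
  else list(value = g[i], k2 = grid[i])
}

#' Maximal growth rate over all spatial frequencies
#'
#' @inheritParams dispersion
#' @return List with `value` (the supremum of the dispersion relation over
#'   `k > 0`) and `k_max` (the frequency attaining it).
#' @export
max_growth_rate <- function(system, steady_state,
                            d = system$D_v / system$D_u) {
  x <- ss_vector(steady_state)
  J <- reaction_jacobian(system, x)
  Dvec <- diffusion_coefs(system, d)
  mg <- max_growth(J, Dvec, max(system$beta), system$D_u)
  list(value = mg$value, k_max = sqrt(mg$k2))
}

#' Critical diffusion ratio at the Turing bifurcation
#'
#' Bisects the inhibitor-to-activator diffusion ratio `d = D_v/D_u` for the
#' value `d*` at which the maximal growth rate over spatial frequencies
#' first becomes positive: just above `d*` the homogeneous steady state is
#' Turing unstable, just below it is stable. The reaction Jacobian must be
#' stable. If the system is still stable at the upper bracket limit, `Inf`
#' is returned (no Turing bifurcation in the bracket).
#'
#' @inheritParams dispersion
#' @param d_bracket Search bracket for `d` (default `c(1, 1e4)`).
#' @param tol Relative bisection tolerance (default 1e-6).
#' @return `d*` as a number (possibly `Inf`), with attribute `k_star` (the
#'   critical frequency) when finite.
#' @export
critical_diffusion_ratio <- function(system, steady_state,
                                     d_bracket = c(1, 1e4), tol = 1e-6) {
  x <- ss_vector(steady_state)
  J <- reaction_jacobian(system, x)
  if (max_re_eig(J) >= -STAB_MARGIN)
    stop("reaction Jacobian is not stable; no Turing bifurcation analysis",
         call. = FALSE)
  Dvec_at <- function(d) diffusion_coefs(system, d)
  bscale <- max(system$beta)
  sup_at <- function(d) max_growth(J, Dvec_at(d), bscale, system$D_u)$value
  lo <- d_bracket[1]; hi <- d_bracket[2]
  if (sup_at(lo) > 0)
    stop("system already Turing unstable at lower bracket d = ", lo,
         call. = FALSE)
  if (sup_at(hi) < 0) return(Inf)
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (sup_at(mid) > 0) hi <- mid else lo <- mid
  }
  dstar <- sqrt(lo * hi)
  structure(dstar, k_star = max_growth(J, Dvec_at(hi), bscale,
                                       system$D_u)$k2^0.5)
}

#' Check admissibility of a multigenerational parameter set
#'
#' A parameter set is admissible at diffusion ratio `d` when parent A,
#' parent B, and the F1 hybrid all have a unique, linearly stable
#' homogeneous steady state, and the critical diffusion ratios order as
#' `d*_F1 < d < min(d*_A, d*_B)`: the parents are Turing stable (solid
#' petals) while the F1 hybrid is Turing unstable (spotted petals) at the
#' shared `d`.
#'
#' @param params A `mg_params` parameter set.
#' @param d Diffusion ratio to test (default `D_v/D_u` from `params`).
#' @param d_bracket Bracket passed to [critical_diffusion_ratio()].
#' @return A list of class `admissibility_report`: `d_star_A`, `d_star_B`,
#'   `d_star_F1`, `d_used`, `verdict`, and `reasons` (character vector of
#'   failed requirements, empty when admissible).
#' @export
check_admissibility <- function(params, d = params$D_v / params$D_u,
                                d_bracket = c(1, 1e4)) {
  params <- validate_params(params)
  core <- dstar_parents_f1(params, d_bracket)
  dstar <- core$dstar
  reasons <- core$reasons
  if (!length(reasons) && is.finite(d)) {
    if (!is.finite(dstar["F1"]))
      reasons <- c(reasons, "F1: no Turing bifurcation in bracket")
    else {
      if (!(dstar["F1"] < d)) reasons <- c(reasons, "d <= d_star_F1")
      if (!(d < min(dstar[c("A", "B")])))
        reasons <- c(reasons, "d >= min(d_star_A, d_star_B)")
    }
  }
  structure(list(
    d_star_A = unname(dstar["A"]), d_star_B = unname(dstar["B"]),
    d_star_F1 = unname(dstar["F1"]), d_used = d,
    verdict = length(reasons) == 0L && is.finite(d), reasons = reasons),
    class = "admissibility_report")
}

# d* and stability screening for parent A, parent B and the F1 hybrid
dstar_parents_f1 <- function(params, d_bracket = c(1, 1e4)) {
  genos <- c(A = "U:AA,V:AA", B = "U:BB,V:BB", F1 = "U:AB,V:AB")
  dstar <- c(A = NA_real_, B = NA_real_, F1 = NA_real_)
  reasons <- character()
  for (nm in names(genos)) {
    sys <- build_system(params, genos[[nm]])
    ss <- tryCatch(find_steady_state(sys), error = function(e) e)
    if (inherits(ss, "error")) {
      reasons <- c(reasons, paste0(nm, ": ", conditionMessage(ss)))
      next
    }
    if (!ss$unique) {
      reasons <- c(reasons, paste0(nm, ": multiple steady states"))
      next
    }
    J <- reaction_jacobian(sys, ss$concentrations)
    if (max_re_eig(J) >= -STAB_MARGIN) {
      reasons <- c(reasons, paste0(nm, ": reaction Jacobian unstable"))
      next
    }
    dstar[nm] <- as.numeric(critical_diffusion_ratio(sys, ss, d_bracket))
  }
  list(dstar = dstar, reasons = reasons)
}

#' @export
print.admissibility_report <- function(x, ...) {
  cat(sprintf("admissibility at d = %.4g: %s\n", x$d_used,
              if (x$verdict) "ADMISSIBLE" else "not admissible"))
  cat(sprintf("  d*_A = %.6g, d*_B = %.6g, d*_F1 = %.6g\n",
              x$d_star_A, x$d_star_B, x$d_star_F1))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = "; "),
                             "\n")
  invisible(x)
}

# JSON-friendly representation (Inf encoded as string sentinel)
report_to_list <- function(x) {
  enc <- function(v) if (is.null(v) || is.na(v)) NULL
  else if (is.infinite(v)) "Inf" else v
  list(d_star_A = enc(x$d_star_A), d_star_B = enc(x$d_star_B),
       d_star_F1 = enc(x$d_star_F1), d_used = x$d_used,
       verdict = x$verdict, reasons = as.list(x$reasons))
}
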