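# Phenotype readout of simulated fields. Total activator concentration is
# the proxy for anthocyanin pigment; a field is "patterned" when its spatial
# coefficient of variation exceeds a threshold, the dominant wavelength is
# read off the radially averaged power spectrum, and spots are counted as
# connected components above the mid-level set.

#' Classify a simulated field as patterned or solid
#'
#' Computes summary statistics of the total activator concentration
#' (`u + uh`): a field is patterned when its spatial coefficient of
#' variation exceeds `threshold` (Turing patterns and roundoff-level
#' inhomogeneity differ by orders of magnitude on this scale, so the
#' threshold is not delicate). For patterned fields the dominant wavelength
#' is the peak of the radially averaged power spectrum and spots are
#' connected components above the `(max + min) / 2` level; a pattern whose
#' largest component spans more than a quarter of the domain is flagged
#' labyrinthine.
#'
#' @param field A `field2d`, or a bare numeric matrix of total activator.
#' @param threshold Coefficient-of-variation threshold (default 0.05).
#' @param dx Grid spacing, taken from the field when available.
#' @return A list of class `phenotype_report`: `patterned`,
#'   `mean_activator`, `min_activator`, `max_activator`, `amplitude`, `cv`,
#'   `dominant_wavelength` and `spot_count` (patterned fields only, else
#'   `NA`), `labyrinthine`, and `reliable` (`FALSE` when the field did not
#'   converge).
#' @export
classify_field <- function(field, threshold = 0.05, dx = NULL) {
  if (inherits(field, "field2d")) {
    ut <- activator_total(field)
    dx <- dx %||% field$dx
    reliable <- !isFALSE(field$converged) || isTRUE(field$saturated)
  } else {
    ut <- as.matrix(field)
    dx <- dx %||% 1
    reliable <- TRUE
  }
  mu <- mean(ut)
  cv <- stats::sd(ut) / mu
  patterned <- is.finite(cv) && cv > threshold
  wl <- NA_real_
  nspots <- NA_integer_
  laby <- FALSE
  if (patterned) {
    wl <- dominant_wavelength(ut, dx)
    cc <- count_spots(ut)
    nspots <- cc$count
    laby <- cc$labyrinthine
  }
  structure(list(patterned = patterned, mean_activator = mu,
                 min_activator = min(ut), max_activator = max(ut),
                 amplitude = max(ut) - min(ut), cv = cv,
                 dominant_wavelength = wl, spot_count = nspots,
                 labyrinthine = laby, reliable = reliable),
            class = "phenotype_report")
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat(sprintf("%s (cv = %.4g)%s\n",
              if (x$patterned) "PATTERNED" else "solid", x$cv,
              if (!x$reliable) " [non-converged field: unreliable]" else ""))
  cat(sprintf("  activator mean %.5g, range [%.5g, %.5g]\n",
              x$mean_activator, x$min_activator, x$max_activator))
  if (x$patterned)
    cat(sprintf("  dominant wavelength %.4g, %d spot(s)%s\n",
                x$dominant_wavelength, x$spot_count,
                if (x$labyrinthine) " (labyrinthine)" else ""))
  invisible(x)
}

#' Dominant wavelength from the radially averaged power spectrum
#'
#' The 2D power spectrum of the mean-subtracted field is binned by radial
#' mode number; the returned wavelength is `L / b` where `L` is the domain
#' side and `b` the peak bin, so resolution is one spectral bin.
#'
#' @param mat Numeric matrix.
#' @param dx Grid spacing.
#' @return Wavelength (length units).
#' @export
dominant_wavelength <- function(mat, dx = 1) {
  nx <- nrow(mat); ny <- ncol(mat)
  P <- Mod(stats::fft(mat - mean(mat)))^2
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx   # cycles per sample
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  q <- sqrt(outer(fx^2, fy^2, `+`)) / dx                 # cycles per length
  dq <- 1 / (max(nx, ny) * dx)                           # bin width
  bin <- round(q / dq)
  pw <- tapply(as.vector(P), as.vector(bin), sum)
  pw <- pw[names(pw) != "0"]
  b <- as.numeric(names(pw)[which.max(pw)])
  1 / (b * dq)
}

#' Count spots as connected components above the mid level
#'
#' Thresholds at `(max + min) / 2` and labels connected components
#' (EBImage). A largest component covering more than 25% of the domain
#' marks the pattern labyrinthine rather than spotted.
#'
#' @param mat Numeric matrix.
#' @return List with `count`, `labyrinthine`, and `labels` (label matrix).
#' @export
count_spots <- function(mat) {
  level <- (max(mat) + min(mat)) / 2
  mask <- mat > level
  labels <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mat), ncol(mat)))
  n <- max(labels)
  biggest <- if (n > 0) max(tabulate(labels[labels > 0])) else 0
  list(count = as.integer(n),
       labyrinthine = biggest > 0.25 * length(mat),
       labels = labels)
}

#' Render a field as a yellow-to-red image
#'
#' Maps total activator concentration onto a yellow (low) to red (high)
#' pseudocolor ramp over a fixed range, so panels sharing `range` are
#' directly comparable.
#'
#' @param field A `field2d` or numeric matrix.
#' @param range Numeric `c(lo, hi)` for the color scale (default the field's
#'   own range; a degenerate range renders uniform yellow).
#' @param path Optional PNG output path.
#' @return The RGB array (`ny x nx x 3`), invisibly.
#' @export
render_field <- function(field, range = NULL, path = NULL) {
  ut <- if (inherits(field, "field2d")) activator_total(field) else
    as.matrix(field)
  range <- range %||% base::range(ut)
  span <- range[2] - range[1]
  z <- if (span <= 0) matrix(0, nrow(ut), ncol(ut)) else
    pmin(pmax((ut - range[1]) / span, 0), 1)
  # yellow (1,1,0) -> red (1,0,0)
  img <- array(0, c(ncol(ut), nrow(ut), 3))
  img[, , 1] <- 1
  img[, , 2] <- t(1 - z)
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}

#' Simulate and classify all nine F2 genotypes
#'
#' Runs the contracted reaction-diffusion system of every F2 genotype of
#' the cross (the 3 x 3 grid of locus-U by locus-V states) at a shared
#' diffusion ratio and seed, classifies each field, and records for each
#' genotype the linear-theory verdict (Turing unstable at `d`) next to the
#' simulated verdict. The diagonal recapitulates parent A, the F1 hybrid,
#' and parent B exactly (same systems, same seed as standalone runs).
#' Refuses parameter sets that are not admissible at `d`.
#'
#' @param params A `mg_params` set.
#' @param d Diffusion ratio (default `D_v/D_u` from `params`).
#' @param config A [sim_config()] shared by all panels.
#' @param dir Optional directory: per-genotype PNGs and a 3 x 3 composite
#'   PNG are written there.
#' @param check Set `FALSE` to skip the admissibility guard.
#' @param stop_when Stopping rule passed to [run_to_steady()] (default
#'   `"saturated"`: classification needs amplitude and wavelength, not the
#'   final spot arrangement).
#' @return A list of class `f2_grid`: `panels` (named list per genotype
#'   with `field`, `report`, `linear_unstable`, `growth_rate`), `d`,
#'   `range` (shared color range), and `composite` (RGB array).
#' @export
f2_grid <- function(params, d = params$D_v / params$D_u,
                    config = sim_config(), dir = NULL, check = TRUE,
                    stop_when = "saturated") {
  params <- validate_params(params)
  if (check) {
    rep <- check_admissibility(params, d)
    if (!rep$verdict)
      stop("parameter set not admissible at d = ", signif(d, 4), ": ",
           paste(rep$reasons, collapse = "; "), call. = FALSE)
  }
  states <- c("AA", "AB", "BB")
  panels <- list()
  for (gv in states) for (gu in states) {
    g <- sprintf("U:%s,V:%s", gu, gv)
    sys <- build_system(params, g)
    ss <- find_steady_state(sys)
    mg <- max_growth_rate(sys, ss, d)
    field <- run_to_steady(sys, d, config, steady_state = ss,
                           stop_when = stop_when)
    panels[[g]] <- list(field = field, report = classify_field(field),
                        linear_unstable = mg$value > 0,
                        growth_rate = mg$value, k_max = mg$k_max)
  }
  rng <- base::range(unlist(lapply(panels, function(p)
    base::range(activator_total(p$field)))))
  composite <- compose_grid(panels, states, rng)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (g in names(panels))
      render_field(panels[[g]]$field, rng,
                   file.path(dir, paste0(gsub("[:,]", "_", g), ".png")))
    png::writePNG(composite, file.path(dir, "f2_grid.png"))
  }
  structure(list(panels = panels, d = d, range = rng,
                 composite = composite), class = "f2_grid")
}

# assemble the 3x3 composite image, U states across, V states down
compose_grid <- function(panels, states, rng, pad = 2) {
  one <- render_field(panels[[1]]$field, rng)
  h <- dim(one)[1]; w <- dim(one)[2]
  H <- 3 * h + 4 * pad; W <- 3 * w + 4 * pad
  img <- array(1, c(H, W, 3))
  for (i in seq_along(states)) for (j in seq_along(states)) {
    g <- sprintf("U:%s,V:%s", states[j], states[i])
    tile <- render_field(panels[[g]]$field, rng)
    r0 <- pad + (i - 1) * (h + pad)
    c0 <- pad + (j - 1) * (w + pad)
    img[r0 + seq_len(h), c0 + seq_len(w), ] <- tile
  }
  img
}

#' @export
print.f2_grid <- function(x, ...) {
  cat(sprintf("F2 grid at d = %.4g\n", x$d))
  for (g in names(x$panels)) {
    p <- x$panels[[g]]
    cat(sprintf("  %s: %s (linear: %s)\n", g,
                if (p$report$patterned) "patterned" else "solid",
                if (p$linear_unstable) "Turing unstable" else "stable"))
  }
  invisible(x)
}
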