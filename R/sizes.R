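#' Binned nanoparticle size distribution
#'
#' A Zetasizer-style size-class table: ordered class edges (nm, diameters)
#' and per-class relative frequencies in percent. This is the sampling
#' substrate for polydisperse nanoparticle populations; monodisperse
#' populations are the degenerate single zero-width class.
#'
#' @param class_edges Strictly increasing class boundaries in nm
#'   (length = number of classes + 1). A single zero-width class
#'   (`c(d, d)`) is allowed and denotes a monodisperse population.
#' @param class_weights Per-class relative frequency in percent; must be
#'   non-negative and sum to 100 within 0.1%.
#' @param label Optional text label.
#' @return An object of class `size_distribution`.
#' @export
#' @examples
#' size_distribution(c(90, 110), 100, "narrow")
size_distribution <- function(class_edges, class_weights, label = "") {
  class_edges <- as.numeric(class_edges)
  class_weights <- as.numeric(class_weights)
  n <- length(class_weights)
  if (n < 1L) stop("at least one size class is required")
  if (length(class_edges) != n + 1L)
    stop("class_edges must have one more entry than class_weights")
  mono <- n == 1L && class_edges[1] == class_edges[2]
  if (!mono && any(diff(class_edges) <= 0))
    stop("class_edges must be strictly increasing")
  if (any(class_edges < 0)) stop("class edges must be non-negative diameters")
  if (any(class_weights < 0)) stop("class_weights must be >= 0")
  s <- sum(class_weights)
  if (s <= 0) stop("class_weights must have positive total")
  if (abs(s - 100) > 0.1) {
    if (abs(s - 100) < 1) {
      warning(sprintf("class weights sum to %.3f%%; renormalising to 100%%", s))
      class_weights <- class_weights * 100 / s
    } else {
      stop(sprintf("class weights sum to %.3f%%, off by >= 1%%", s))
    }
  } else if (s != 100) {
    class_weights <- class_weights * 100 / s
  }
  structure(list(class_edges = class_edges, class_weights = class_weights,
                 label = label, monodisperse = mono),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> %s: %d class(es), %g-%g nm\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              length(x$class_weights),
              min(x$class_edges), max(x$class_edges)))
  invisible(x)
}

#' Monodisperse population of a single diameter
#' @param diameter Diameter in nm.
#' @return A degenerate one-class [size_distribution()].
#' @export
monodisperse <- function(diameter) {
  size_distribution(c(diameter, diameter), 100,
                    label = sprintf("monodisperse %g nm", diameter))
}

#' Parse a DLS size-class table from CSV
#'
#' Expects columns `lower_nm`, `upper_nm`, `percent`. Rows may be in any
#' order; they are sorted by lower edge and must tile contiguously.
#'
#' @param file Path to a CSV file.
#' @return A [size_distribution()].
#' @export
#' @examples
#' f <- system.file("extdata", "synthetic_dls_100nm_pdi0.1.csv",
#'                  package = "capsim")
#' parse_dls_table(f)
parse_dls_table <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("lower_nm", "upper_nm", "percent")
  if (!all(need %in% names(tab)))
    stop("DLS CSV must have columns lower_nm, upper_nm, percent")
  tab <- tab[order(tab$lower_nm), , drop = FALSE]
  for (i in seq_len(nrow(tab))) {
    if (tab$upper_nm[i] <= tab$lower_nm[i])
      stop(sprintf("row %d: upper_nm must exceed lower_nm", i))
    if (tab$percent[i] < 0)
      stop(sprintf("row %d: negative percent", i))
    if (i > 1L && abs(tab$lower_nm[i] - tab$upper_nm[i - 1L]) > 1e-9)
      stop(sprintf("row %d: classes are not contiguous", i))
  }
  size_distribution(c(tab$lower_nm, tab$upper_nm[nrow(tab)]), tab$percent,
                    label = basename(file))
}

#' Write a size distribution as a DLS-style CSV
#' @param dist A [size_distribution()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_dls_table <- function(dist, file) {
  n <- length(dist$class_weights)
  utils::write.csv(data.frame(lower_nm = dist$class_edges[seq_len(n)],
                              upper_nm = dist$class_edges[-1L],
                              percent = dist$class_weights),
                   file, row.names = FALSE)
  invisible(file)
}

#' Within-class density endpoint values
#'
#' The class-interior density is piecewise linear; its value at an internal
#' class edge is interpolated from the neighbouring classes' mean densities
#' (weight / width), so that neighbouring classes shape where inside a class
#' the mass sits. Endpoint values are rescaled per class so the class mass
#' still equals the class weight exactly.
#' @noRd
class_edge_densities <- function(dist) {
  n <- length(dist$class_weights)
  w <- dist$class_weights
  widths <- diff(dist$class_edges)
  dens <- w / widths                        # mean density per class
  lo <- hi <- numeric(n)
  for (i in seq_len(n)) {
    lo[i] <- if (i == 1L) dens[1L] else (dens[i - 1L] + dens[i]) / 2
    hi[i] <- if (i == n)  dens[n]  else (dens[i] + dens[i + 1L]) / 2
    m <- (lo[i] + hi[i]) / 2                # current class mass / width
    if (m > 0) {
      sc <- dens[i] / m
      lo[i] <- lo[i] * sc
      hi[i] <- hi[i] * sc
    }
  }
  list(lo = lo, hi = hi)
}

#' Sample nanoparticle diameters from a size distribution
#'
#' The size class is chosen by inverse-CDF on the class weights; the diameter
#' within the class is drawn from a piecewise-linear (trapezoidal) density
#' whose endpoint values are interpolated from the neighbouring classes'
#' weights.
#'
#' @param dist A [size_distribution()].
#' @param n Number of samples (>= 1).
#' @return Numeric vector of `n` diameters in nm, all within the class-edge
#'   range.
#' @export
#' @examples
#' set.seed(1)
#' d <- sample_sizes(synthetic_dls(100, 0.1), 1000)
sample_sizes <- function(dist, n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (dist$monodisperse) return(rep(dist$class_edges[1L], n))
  w <- dist$class_weights / 100
  cls <- findInterval(stats::runif(n), cumsum(w)) + 1L
  cls <- pmin(cls, length(w))
  ed <- class_edge_densities(dist)
  a <- dist$class_edges[cls]
  b <- dist$class_edges[cls + 1L]
  fa <- ed$lo[cls]
  fb <- ed$hi[cls]
  u <- stats::runif(n)
  # inverse CDF of a linear density on [a, b] with endpoint values (fa, fb)
  out <- numeric(n)
  flat <- abs(fb - fa) <= 1e-12 * pmax(fa, fb, 1e-300)
  out[flat] <- a[flat] + u[flat] * (b[flat] - a[flat])
  if (any(!flat)) {
    i <- !flat
    # solve (fa*t + (fb-fa)*t^2/2) / ((fa+fb)/2) = u with t in [0,1]
    A <- (fb[i] - fa[i]) / 2
    B <- fa[i]
    C <- -u[i] * (fa[i] + fb[i]) / 2
    t <- (-B + sqrt(pmax(B^2 - 4 * A * C, 0))) / (2 * A)
    out[i] <- a[i] + pmin(pmax(t, 0), 1) * (b[i] - a[i])
  }
  out
}

#' Synthetic DLS-like size distribution
#'
#' Builds a lognormal intensity-style distribution with a stated mean
#' diameter and polydispersity index (pdi = variance / mean^2), binned into
#' logarithmically spaced size classes following the Zetasizer export
#' convention. Stands in for instrument-measured DLS curves.
#'
#' @param mean_diameter Mean diameter in nm (> 0).
#' @param pdi Polydispersity index in [0, 0.5).
#' @param n_classes Number of log-spaced classes (>= 5). Default 26.
#' @param range Diameter range covered by the class grid (nm).
#'   Default `c(1, 1000)`.
#' @return A [size_distribution()] whose weights are the lognormal mass in
#'   each class (classes with negligible mass are trimmed).
#' @export
synthetic_dls <- function(mean_diameter, pdi, n_classes = 26,
                          range = c(1, 1000)) {
  if (mean_diameter <= 0) stop("mean_diameter must be > 0")
  if (pdi < 0 || pdi >= 0.5) stop("pdi must lie in [0, 0.5)")
  if (n_classes < 5) stop("n_classes must be >= 5")
  edges <- exp(seq(log(range[1]), log(range[2]), length.out = n_classes + 1L))
  if (pdi == 0) {
    # degenerate: all mass in the class containing the mean
    k <- findInterval(mean_diameter, edges, rightmost.closed = TRUE)
    k <- min(max(k, 1L), n_classes)
    w <- numeric(n_classes)
    w[k] <- 100
  } else {
    sdlog <- sqrt(log1p(pdi))
    meanlog <- log(mean_diameter) - sdlog^2 / 2
    cdf <- stats::plnorm(edges, meanlog, sdlog)
    w <- diff(cdf)
    w <- 100 * w / sum(w)
  }
  keep <- w > 1e-9
  first <- which(keep)[1L]
  last <- which(keep)[length(which(keep))]
  idx <- first:last
  size_distribution(edges[c(idx, last + 1L)], 100 * w[idx] / sum(w[idx]),
                    label = sprintf("synthetic DLS %g nm pdi %g",
                                    mean_diameter, pdi))
}

#' Volume of a spherical nanoparticle
#' @param diameter Diameter in nm (> 0); vectorised.
#' @return Volume in nm^3, `(pi/6) d^3`.
#' @export
particle_volume <- function(diameter) {
  if (any(diameter <= 0)) stop("diameter must be > 0")
  pi / 6 * diameter^3
}
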