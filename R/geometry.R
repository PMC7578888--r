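#' Model multichromophore geometries
#'
#' The model systems place a single acceptor at the origin surrounded by
#' `n_D` identical donors located as far apart from each other as possible:
#' two antipodal donors (D2A) or the vertices of a platonic solid
#' (D4A tetrahedron, D6A octahedron, D8A cube, D12A icosahedron, D20A
#' dodecahedron). Only the *ratios* of donor-donor distances matter for the
#' kinetics: the donor-acceptor and nearest-neighbour donor-donor distances
#' are set independently (in units of the respective Forster radius) when a
#' configuration is sampled, and farther donor pairs scale by the
#' polyhedron's diagonal-to-edge ratios.
#'
#' A `model_geometry` object holds:
#' \describe{
#'   \item{name}{catalog label.}
#'   \item{n_donors}{number of donors `n_D`.}
#'   \item{donor_directions}{`n_D x 3` matrix of unit vectors from the
#'     acceptor (placeholders for distance-only pseudomodels).}
#'   \item{pair_ratio}{symmetric matrix of inter-donor distances divided by
#'     the nearest-neighbour inter-donor distance (0 on the diagonal).}
#'   \item{shells}{per donor, a list of integer vectors grouping the other
#'     donors into nearest, second-nearest, ... shells.}
#'   \item{shell_ratios}{per donor, the distance ratio of each shell.}
#'   \item{n_nd}{per-donor nearest-shell size (`n_ND`).}
#'   \item{n_nd_catalog}{the nearest-neighbour count as conventionally
#'     quoted for the model (differs from the geometric value only for D2A,
#'     where the whole two-donor nearest-neighbour network is sometimes
#'     counted as 2).}
#'   \item{distance_only}{`TRUE` for abstract pseudomodels whose
#'     coordinates are placeholders.}
#' }
#'
#' @param name one of `"D1A"`, `"D2A"`, `"D4A"`, `"D6A"`, `"D8A"`,
#'   `"D12A"`, `"D20A"`.
#' @return a `model_geometry` object.
#' @examples
#' g <- build_model("D12A")
#' g$n_nd # 5 nearest neighbours per donor on the icosahedron
#' @export
build_model <- function(name) {
  coords <- switch(name,
    D1A = matrix(c(0, 0, 1), 1, 3),
    D2A = rbind(c(0, 0, 1), c(0, 0, -1)),
    D4A = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
    D6A = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
    D8A = as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
    D12A = icosahedron_vertices(),
    D20A = dodecahedron_vertices(),
    stop("unknown model '", name, "'; supported models: ",
         paste(model_catalog_names(), collapse = ", "), call. = FALSE)
  )
  coords <- coords / sqrt(rowSums(coords^2))
  dimnames(coords) <- NULL
  n_nd_catalog <- c(D1A = 0L, D2A = 2L, D4A = 3L, D6A = 4L, D8A = 3L,
                    D12A = 5L, D20A = 3L)[[name]]
  new_model_geometry(name, coords, n_nd_catalog = n_nd_catalog,
                     distance_only = FALSE)
}

#' Equidistant pseudomodel where every donor pair is a nearest pair
#'
#' An abstract distance model in which all `n` donors are equally spaced
#' from each other, so `n_ND = n - 1`. For `n > 4` no 3-D embedding exists;
#' the kinetics consume only distances, never coordinates, so the stored
#' directions are placeholders and the model is flagged `distance_only`.
#'
#' @param n_donors number of donors, at least 2.
#' @return a `model_geometry` object named `EQ<n>`.
#' @examples
#' build_equidistant_model(12)$n_nd[1] # 11
#' @export
build_equidistant_model <- function(n_donors) {
  if (!is.numeric(n_donors) || length(n_donors) != 1 || n_donors < 2 ||
      n_donors != round(n_donors))
    stop("n_donors must be a single integer >= 2", call. = FALSE)
  n <- as.integer(n_donors)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  coords <- cbind(cos(ang), sin(ang), 0) # placeholder unit vectors
  ratio <- matrix(1, n, n)
  diag(ratio) <- 0
  new_model_geometry(paste0("EQ", n), coords, pair_ratio = ratio,
                     n_nd_catalog = n - 1L, distance_only = TRUE)
}

model_catalog_names <- function() {
  c("D1A", "D2A", "D4A", "D6A", "D8A", "D12A", "D20A")
}

icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi))
  rbind(v, v[, c(3, 1, 2)], v[, c(2, 3, 1)])
}

dodecahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  v <- rbind(c(0, 1 / phi, phi), c(0, 1 / phi, -phi),
             c(0, -1 / phi, phi), c(0, -1 / phi, -phi))
  rbind(cube, v, v[, c(3, 1, 2)], v[, c(2, 3, 1)])
}

# Relative tolerance grouping two pair ratios into the same shell;
# floating-point vertex coordinates motivate a loose-but-safe 1e-6.
SHELL_TOL <- 1e-6

new_model_geometry <- function(name, coords, pair_ratio = NULL,
                               n_nd_catalog, distance_only) {
  n <- nrow(coords)
  if (is.null(pair_ratio)) {
    d <- as.matrix(stats::dist(coords))
    dimnames(d) <- NULL
    pair_ratio <- if (n > 1) d / min(d[upper.tri(d)]) else matrix(0, 1, 1)
  }
  shells <- vector("list", n)
  shell_ratios <- vector("list", n)
  n_nd <- integer(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    if (length(others) == 0) {
      shells[[i]] <- list()
      shell_ratios[[i]] <- numeric(0)
      next
    }
    r <- pair_ratio[i, others]
    ord <- order(r)
    grp <- cumsum(c(TRUE, diff(r[ord]) / r[ord][-length(r)] > SHELL_TOL))
    shells[[i]] <- split(others[ord], grp)
    names(shells[[i]]) <- NULL
    shell_ratios[[i]] <- vapply(shells[[i]], function(s) mean(pair_ratio[i, s]),
                                numeric(1))
    n_nd[i] <- length(shells[[i]][[1]])
  }
  structure(list(name = name, n_donors = n, donor_directions = coords,
                 pair_ratio = pair_ratio, shells = shells,
                 shell_ratios = shell_ratios, n_nd = n_nd,
                 n_nd_catalog = n_nd_catalog, distance_only = distance_only),
            class = "model_geometry")
}

#' @export
print.model_geometry <- function(x, ...) {
  cat("<model_geometry> ", x$name, ": ", x$n_donors, " donor(s)",
      if (x$distance_only) " [distance-only]", "\n", sep = "")
  if (x$n_donors > 1)
    cat("  n_ND per donor:", paste(unique(x$n_nd), collapse = "/"),
        " shell ratios (donor 1):",
        paste(signif(x$shell_ratios[[1]], 6), collapse = ", "), "\n")
  invisible(x)
}

# Unordered donor pairs of a geometry as an integer matrix (i < j).
donor_pairs <- function(geometry) {
  n <- geometry$n_donors
  if (n < 2) return(matrix(integer(0), 0, 2))
  t(utils::combn(n, 2))
}

#' Export a geometry as a JSON document
#'
#' @param geometry a `model_geometry`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
geometry_to_json <- function(geometry, path = NULL) {
  doc <- list(name = geometry$name, n_donors = geometry$n_donors,
              pair_ratio = geometry$pair_ratio,
              shells = geometry$shells, n_nd = geometry$n_nd,
              n_nd_catalog = geometry$n_nd_catalog,
              distance_only = geometry$distance_only)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
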