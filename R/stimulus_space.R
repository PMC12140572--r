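#' The eight-stimulus chroma/brightness design space
#'
#' A `triad_space` holds the coordinates of the eight stimuli used in the
#' triad ("odd one out") task: Munsell chroma (saturation) on one axis and
#' Munsell value (brightness) on the other.  Psychologically, two units of
#' chroma are equivalent to one unit of brightness, so all distance
#' computations first multiply chroma by `chroma_weight` (default 0.5).
#'
#' @param coords data frame with columns `stimulus`, `chroma`, `brightness`,
#'   one row per stimulus id 1..8.
#' @param chroma_weight scalar multiplier applied to chroma before any
#'   distance computation.  The default 0.5 encodes the 2:1
#'   chroma-to-brightness equivalence of the Munsell system.
#' @param validate_ranges if `TRUE` (the default for Munsell designs),
#'   require chroma within \[4, 12\] and brightness within \[2, 6\].
#'   Spaces derived from multidimensional scaling are on an arbitrary scale
#'   and are constructed with `validate_ranges = FALSE` and
#'   `chroma_weight = 1`.
#' @return an object of class `triad_space`: a list with elements `coords`
#'   (data frame), `chroma_weight`, and `scaled` (an 8 x 2 matrix of
#'   weighted coordinates, rownames = stimulus ids).
#' @export
triad_space <- function(coords, chroma_weight = 0.5, validate_ranges = TRUE) {
  required <- c("stimulus", "chroma", "brightness")
  if (!is.data.frame(coords) || !all(required %in% names(coords)))
    stop("coords must be a data frame with columns stimulus, chroma, brightness")
  coords <- coords[required]
  if (!all(vapply(coords, is.numeric, logical(1))))
    stop("non-numeric entry in coordinate table")
  if (anyNA(coords))
    stop("non-numeric entry in coordinate table")
  ids <- sort(coords$stimulus)
  if (length(ids) != 8L || !identical(as.integer(ids), 1:8))
    stop("missing stimulus: need exactly one row for each stimulus id 1..8")
  if (validate_ranges) {
    if (any(coords$chroma < 4 | coords$chroma > 12))
      stop("chroma coordinate outside [4, 12]")
    if (any(coords$brightness < 2 | coords$brightness > 6))
      stop("brightness coordinate outside [2, 6]")
  }
  coords <- coords[order(coords$stimulus), ]
  coords$stimulus <- as.integer(coords$stimulus)
  rownames(coords) <- NULL
  scaled <- cbind(chroma = coords$chroma * chroma_weight,
                  brightness = coords$brightness)
  rownames(scaled) <- coords$stimulus
  structure(list(coords = coords, chroma_weight = chroma_weight,
                 scaled = scaled),
            class = "triad_space")
}

#' Load a stimulus space from a coordinate CSV
#'
#' The file must have a header `stimulus,chroma,brightness` and one row per
#' stimulus id 1..8.  Values are validated against the Munsell design
#' ranges (chroma 4-12, brightness 2-6).
#'
#' @param path path to the CSV file.
#' @inheritParams triad_space
#' @return a [triad_space].
#' @export
load_space <- function(path, chroma_weight = 0.5) {
  tab <- utils::read.csv(path, colClasses = "numeric")
  triad_space(tab, chroma_weight = chroma_weight)
}

#' The package's built-in design space
#'
#' Coordinates of the eight stimuli, reconstructed from the structural
#' constraints of the published design (each triad has exactly one pair
#' identical on exactly one dimension; the quoted worked examples pin the
#' identity pairs and unidimensional winners).  The reconstruction is
#' validated by the invariant suite rather than read from the original
#' figure, and ships as
#' `inst/extdata/stimulus_coords_reconstructed.csv` so that an alternative
#' transcription (or an MDS-derived space) can be swapped in.
#'
#' @return a [triad_space].
#' @export
default_space <- function() {
  load_space(system.file("extdata", "stimulus_coords_reconstructed.csv",
                         package = "triadfit", mustWork = TRUE))
}

#' Construct a space directly from already-scaled 2-D coordinates
#'
#' Used to feed a multidimensional-scaling solution back into the response
#' models: the configuration axes are treated as (psychological) chroma and
#' brightness and no further chroma weighting is applied.
#'
#' @param xy an 8 x 2 matrix, rows ordered (or rownamed) by stimulus id.
#' @return a [triad_space] with `chroma_weight = 1`.
#' @export
space_from_coords <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) != 8L || ncol(xy) != 2L)
    stop("need an 8 x 2 coordinate matrix")
  ids <- if (is.null(rownames(xy))) 1:8 else as.integer(rownames(xy))
  coords <- data.frame(stimulus = ids, chroma = xy[, 1], brightness = xy[, 2])
  coords <- coords[order(coords$stimulus), ]
  triad_space(coords, chroma_weight = 1, validate_ranges = FALSE)
}

#' The eight logical triads of the design
#'
#' @return a list of integer vectors of length 3 (stimulus ids), named by
#'   the conventional triad labels.
#' @export
design_triads <- function() {
  tr <- list(c(1L, 3L, 7L), c(1L, 5L, 7L), c(2L, 4L, 8L), c(2L, 6L, 8L),
             c(1L, 2L, 3L), c(1L, 2L, 4L), c(5L, 7L, 8L), c(6L, 7L, 8L))
  names(tr) <- vapply(tr, paste, "", collapse = "-")
  tr
}

#' Identity structure of a logical triad
#'
#' Finds the pair of triad members that share a coordinate on exactly one
#' dimension.  The design guarantees each triad has exactly one such pair;
#' a triad with zero or several identical pairs raises an error.
#'
#' @param members integer vector of 3 distinct stimulus ids.
#' @param space a [triad_space].
#' @return list with `identity_dimension` (`"chroma"` or `"brightness"`)
#'   and `identity_pair` (sorted integer vector of length 2).
#' @export
triad_identity <- function(members, space) {
  stopifnot(inherits(space, "triad_space"))
  if (length(unique(members)) != 3L) stop("triad with duplicate members")
  co <- space$coords
  pairs <- utils::combn(sort(as.integer(members)), 2)
  hits <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- co[co$stimulus == pairs[1, k], ]
    b <- co[co$stimulus == pairs[2, k], ]
    for (dim in c("chroma", "brightness")) {
      if (a[[dim]] == b[[dim]])
        hits[[length(hits) + 1L]] <- list(pair = pairs[, k], dim = dim)
    }
  }
  if (length(hits) == 0L)
    stop("design violation: no identical pair in triad ",
         paste(members, collapse = "-"))
  if (length(hits) > 1L)
    stop("design violation: multiple identical pairs in triad ",
         paste(members, collapse = "-"))
  list(identity_dimension = hits[[1]]$dim, identity_pair = hits[[1]]$pair)
}

#' Enumerate the physical arrangements of a set of logical triads
#'
#' Each logical triad can be laid out left/middle/right in 3! = 6 ways;
#' the full design of 8 triads therefore yields 48 physically distinct
#' displays.
#'
#' @param triads list of integer vectors of length 3 (distinct ids), as
#'   returned by [design_triads()].
#' @return data frame with columns `triad` (label), `left`, `middle`,
#'   `right`; 6 rows per logical triad.
#' @export
enumerate_instances <- function(triads = design_triads()) {
  if (length(triads) == 0L)
    return(data.frame(triad = character(), left = integer(),
                      middle = integer(), right = integer()))
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  rows <- lapply(triads, function(m) {
    m <- as.integer(m)
    if (length(unique(m)) != 3L) stop("triad with duplicate members")
    data.frame(triad = paste(sort(m), collapse = "-"),
               left = m[perms[, 1]], middle = m[perms[, 2]],
               right = m[perms[, 3]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quadrant membership of the design space
#'
#' The space is split at the midpoints of the design ranges (chroma 8,
#' brightness 4) into four quadrants: LCLB, LCHB, HCLB, HCHB (low/high
#' chroma x low/high brightness).  A stimulus exactly on a midline is
#' assigned the quadrant of its nearest (scaled-distance) off-midline
#' neighbour.
#'
#' @param space a [triad_space].
#' @return named list of integer vectors of stimulus ids, names
#'   `LCLB`, `LCHB`, `HCLB`, `HCHB`.
#' @export
quadrants <- function(space = default_space()) {
  co <- space$coords
  cmid <- 8; bmid <- 4
  lab <- function(ch, br) {
    paste0(if (ch < cmid) "LC" else "HC", if (br < bmid) "LB" else "HB")
  }
  on_mid <- co$chroma == cmid | co$brightness == bmid
  labs <- character(8)
  for (i in seq_len(8)) {
    if (!on_mid[i]) {
      labs[i] <- lab(co$chroma[i], co$brightness[i])
    } else {
      sc <- space$scaled
      d <- sqrt(rowSums((sc - matrix(sc[i, ], 8, 2, byrow = TRUE))^2))
      d[i] <- Inf; d[on_mid] <- Inf
      j <- which.min(d)
      labs[i] <- lab(co$chroma[j], co$brightness[j])
    }
  }
  out <- lapply(c(LCLB = "LCLB", LCHB = "LCHB", HCLB = "HCLB", HCHB = "HCHB"),
                function(l) co$stimulus[labs == l])
  lapply(out, as.integer)
}

#' Drop every triad that touches a quadrant of the space
#'
#' Used for the quadrant-removal sub-analyses: each sub-analysis removes
#' all triads containing any stimulus of one quadrant.  A useful subset
#' must still contain at least one chroma-spanning and one
#' brightness-spanning triad, otherwise unidimensional and
#' overall-similarity responding cannot be told apart; a warning is raised
#' if the remaining set loses that property.
#'
#' @param triads list of logical triads (integer vectors).
#' @param members integer vector of stimulus ids to exclude (e.g. one
#'   element of [quadrants()]).
#' @param space a [triad_space] used to judge diagnosability.
#' @return the filtered list of triads.
#' @export
filter_triads_excluding_quadrant <- function(triads, members,
                                             space = default_space()) {
  keep <- vapply(triads, function(m) !any(m %in% members), logical(1))
  out <- triads[keep]
  if (length(out)) {
    dims <- vapply(out, function(m) triad_identity(m, space)$identity_dimension, "")
    # identity on chroma <=> the triad spans brightness, and vice versa
    if (!("chroma" %in% dims) || !("brightness" %in% dims))
      warning("remaining triads cannot separate unidimensional from ",
              "overall-similarity responding (need both chroma- and ",
              "brightness-spanning triads)")
  }
  out
}
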