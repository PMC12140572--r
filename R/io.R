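#' File round-tripping for trials, ratings and coordinates
#'
#' All tables travel as plain CSV with fixed schemas:
#' trials `participant,condition_ms,block,trial,left,middle,right,response_pos`;
#' ratings `participant,block,left,right,rating`;
#' coordinates `stimulus,chroma,brightness`;
#' similarity matrices as an 8 x 8 matrix CSV with a `stimulus` id column.
#' Readers validate the schema and value ranges and name the offending row
#' on failure; `write_*` followed by `read_*` is the identity on valid
#' data.
#'
#' @name cli_io
NULL

.check_cols <- function(tab, cols, what) {
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop(what, " file is missing columns: ", paste(miss, collapse = ", "))
}

.check_range <- function(tab, col, values, what) {
  bad <- which(!(tab[[col]] %in% values))
  if (length(bad))
    stop(what, " row ", bad[1], ": ", col, " = ", tab[[col]][bad[1]],
         " is out of range")
}

#' @rdname cli_io
#' @param path file path.
#' @return `read_trials`: validated trial data frame.
#' @export
read_trials <- function(path) {
  tab <- utils::read.csv(path)
  .check_cols(tab, c("participant", "condition_ms", "block", "trial",
                     "left", "middle", "right", "response_pos"), "trials")
  for (col in c("left", "middle", "right"))
    .check_range(tab, col, 1:8, "trials")
  .check_range(tab, "block", 1:12, "trials")
  .check_range(tab, "response_pos", 1:3, "trials")
  tab
}

#' @rdname cli_io
#' @param trials trial data frame.
#' @export
write_trials <- function(trials, path) {
  cols <- c("participant", "condition_ms", "block", "trial",
            "left", "middle", "right", "response_pos")
  utils::write.csv(trials[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname cli_io
#' @return `read_ratings`: validated long-form rating data frame.
#' @export
read_ratings <- function(path) {
  tab <- utils::read.csv(path)
  .check_cols(tab, c("participant", "block", "left", "right", "rating"),
              "ratings")
  for (col in c("left", "right")) .check_range(tab, col, 1:8, "ratings")
  .check_range(tab, "rating", 1:9, "ratings")
  tab
}

#' @rdname cli_io
#' @param ratings long-form rating data frame.
#' @export
write_ratings <- function(ratings, path) {
  cols <- c("participant", "block", "left", "right", "rating")
  utils::write.csv(ratings[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname cli_io
#' @return `read_coords`: a [triad_space] (same as [load_space()]).
#' @export
read_coords <- function(path) load_space(path)

#' @rdname cli_io
#' @return `read_similarity`: symmetric 8 x 8 matrix of mean ratings.
#' @export
read_similarity <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  .check_cols(tab, "stimulus", "similarity")
  m <- as.matrix(tab[, as.character(1:8)])
  rownames(m) <- tab$stimulus
  m <- m[as.character(1:8), ]
  if (!isSymmetric(unname(ifelse(is.na(m), 0, m))))
    stop("similarity matrix must be symmetric")
  m
}

#' @rdname cli_io
#' @param m symmetric similarity matrix.
#' @export
write_similarity <- function(m, path) {
  out <- data.frame(stimulus = 1:8, m, check.names = FALSE)
  names(out) <- c("stimulus", 1:8)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
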