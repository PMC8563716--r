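#' Build the Type III rule-plus-exception stimulus set
#'
#' Constructs the 10-flower stimulus set used throughout the package: a
#' Shepard-Hovland-Jenkins Type III assignment over three binary diagnostic
#' dimensions (outer petal colour, outer petal shape, inner petal shape),
#' one binary nondiagnostic dimension (central disc colour), and a binary
#' category label.  Each category contains two prototypes (one per value of
#' the nondiagnostic feature), two rule-followers and one exception.
#'
#' Role geometry on the diagnostic triple (d1, d2, d3): prototypes of
#' opposite categories differ on all three dimensions; a rule-follower
#' differs from its own prototype on exactly one; an exception differs from
#' its own prototype on two and from the opposite prototype on one.
#'
#' The default assignment is one canonical Type III isomorph:
#' A = \{000 (P), 001 (R), 010 (R), 110 (E)\},
#' B = \{111 (P), 101 (R), 011 (R), 100 (E)\}.
#' The default nondiagnostic map makes the category-A exception share its
#' disc colour with its diagnostically nearest own-category neighbours
#' (RA2 and the d4-matched prototype) while the category-B exception does
#' not -- the asymmetry that makes EB "more exceptional" than EA.
#'
#' @param diagnostic Named list giving the diagnostic (d1,d2,d3) triple of
#'   every stimulus id as an integer vector of 0/1.  Defaults to the
#'   canonical assignment above.
#' @param nondiagnostic Named integer vector giving d4 for the ids whose
#'   disc colour is free (`RA1`, `RA2`, `EA`, `RB1`, `RB2`, `EB`).
#'   Prototype d4 values are fixed: `PA1`/`PB1` have d4 = 0,
#'   `PA2`/`PB2` have d4 = 1.
#' @return A tibble of class `stimulus_set` with one row per stimulus:
#'   `id`, `role` (prototype / rule_follower / exception), `category`
#'   (A / B), feature columns `d1`..`d5` (d5 is the category label, A = 0),
#'   and `encoding`, the 10-character padded binary code.
#' @examples
#' stim <- stimulus_set()
#' stim$encoding[stim$id == "PA1"]  # "1010101010"
#' @export
stimulus_set <- function(diagnostic = NULL, nondiagnostic = NULL) {
  default_diag <- list(
    PA1 = c(0L, 0L, 0L), PA2 = c(0L, 0L, 0L),
    RA1 = c(0L, 0L, 1L), RA2 = c(0L, 1L, 0L), EA = c(1L, 1L, 0L),
    PB1 = c(1L, 1L, 1L), PB2 = c(1L, 1L, 1L),
    RB1 = c(1L, 0L, 1L), RB2 = c(0L, 1L, 1L), EB = c(1L, 0L, 0L)
  )
  default_d4 <- c(RA1 = 1L, RA2 = 0L, EA = 0L, RB1 = 0L, RB2 = 1L, EB = 1L)
  diag_map <- default_diag
  if (!is.null(diagnostic)) diag_map[names(diagnostic)] <- diagnostic
  d4_map <- default_d4
  if (!is.null(nondiagnostic)) d4_map[names(nondiagnostic)] <- as.integer(nondiagnostic)

  ids <- c("PA1", "PA2", "RA1", "RA2", "EA", "PB1", "PB2", "RB1", "RB2", "EB")
  roles <- c("prototype", "prototype", "rule_follower", "rule_follower",
             "exception")[c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)]
  cats <- rep(c("A", "B"), each = 5)
  d4_full <- c(PA1 = 0L, PA2 = 1L, PB1 = 0L, PB2 = 1L, d4_map)[ids]

  feats <- purrr::map(ids, function(id) {
    tr <- diag_map[[id]]
    if (is.null(tr) || length(tr) != 3L || !all(tr %in% c(0L, 1L)))
      stop("invalid diagnostic triple for ", id, call. = FALSE)
    tr
  })
  out <- tibble::tibble(
    id = ids,
    role = roles,
    category = cats,
    d1 = purrr::map_int(feats, 1),
    d2 = purrr::map_int(feats, 2),
    d3 = purrr::map_int(feats, 3),
    d4 = as.integer(d4_full),
    d5 = ifelse(cats == "A", 0L, 1L)
  )
  out$encoding <- apply(as.matrix(out[, c("d1", "d2", "d3", "d4", "d5")]),
                        1L, encode_features)
  validate_stimulus_set(out)
  class(out) <- c("stimulus_set", class(out))
  out
}

# padded one-hot pair code: 0 -> "10", 1 -> "01"; convention fixed so the
# category-A prototype with all-zero features encodes "1010101010"
encode_features <- function(feat) {
  stopifnot(length(feat) == 5L, all(feat %in% c(0L, 1L)))
  paste(ifelse(feat == 0L, "10", "01"), collapse = "")
}

#' Encode a stimulus as a length-10 padded binary vector
#'
#' Pair k of the code (units 2k-1, 2k) one-hot encodes feature dimension k:
#' value 0 maps to "10" and value 1 to "01", so the category-A prototype
#' with all-zero features is "1010101010" and exactly 5 of the 10 units are
#' active for every stimulus.
#'
#' @param stimuli A `stimulus_set` tibble (or any tibble with columns
#'   `d1`..`d5`).
#' @return An integer matrix with one row per stimulus and 10 columns,
#'   rownames set to stimulus ids when present.
#' @export
encode_stimuli <- function(stimuli) {
  feats <- as.matrix(stimuli[, c("d1", "d2", "d3", "d4", "d5")])
  enc <- matrix(0L, nrow(feats), 10L)
  for (k in 1:5) {
    enc[, 2L * k - 1L] <- 1L - feats[, k]
    enc[, 2L * k]      <- feats[, k]
  }
  if ("id" %in% names(stimuli)) rownames(enc) <- stimuli$id
  enc
}

#' Decode a padded binary vector back to its five features
#'
#' Inverse of the padded pair code; `decode_encoding(encode_stimuli(s))`
#' recovers the feature columns of `s` exactly.
#'
#' @param encoding A length-10 0/1 vector, a 10-character string of 0/1, or
#'   a matrix of row encodings.
#' @return An integer matrix with columns `d1`..`d5`.
#' @export
decode_encoding <- function(encoding) {
  if (is.character(encoding)) {
    encoding <- t(vapply(encoding,
                         function(s) as.integer(strsplit(s, "")[[1]]),
                         integer(10)))
  }
  if (is.null(dim(encoding))) encoding <- matrix(encoding, nrow = 1L)
  stopifnot(ncol(encoding) == 10L)
  bad <- apply(encoding, 1L, function(e) any(e[c(1, 3, 5, 7, 9)] + e[c(2, 4, 6, 8, 10)] != 1L))
  if (any(bad)) stop("not a valid padded pair code", call. = FALSE)
  out <- encoding[, c(2, 4, 6, 8, 10), drop = FALSE]
  colnames(out) <- paste0("d", 1:5)
  out
}

#' Hamming distance between two stimuli
#'
#' Distance over the three diagnostic dimensions by default, or over
#' diagnostic plus nondiagnostic dimensions (`d1`..`d4`) when
#' `include_nondiagnostic = TRUE`.  The category label never enters.
#'
#' @param stimuli A `stimulus_set`.
#' @param a,b Stimulus ids.
#' @param include_nondiagnostic Include `d4` in the distance?
#' @return Integer Hamming distance.
#' @export
stimulus_distance <- function(stimuli, a, b, include_nondiagnostic = FALSE) {
  cols <- if (include_nondiagnostic) c("d1", "d2", "d3", "d4") else c("d1", "d2", "d3")
  ra <- stimuli[stimuli$id == a, cols]
  rb <- stimuli[stimuli$id == b, cols]
  if (nrow(ra) != 1L || nrow(rb) != 1L)
    stop("unknown stimulus id", call. = FALSE)
  sum(unlist(ra) != unlist(rb))
}

validate_stimulus_set <- function(stim) {
  if (!all(table(stim$role) == c(exception = 2L, prototype = 4L, rule_follower = 4L)[names(table(stim$role))]))
    stop("structural validation: need 4 prototypes, 4 rule-followers, 2 exceptions",
         call. = FALSE)
  diag_cols <- c("d1", "d2", "d3")
  dist3 <- function(a, b) sum(unlist(stim[stim$id == a, diag_cols]) !=
                              unlist(stim[stim$id == b, diag_cols]))
  proto <- function(cat) stim$id[stim$role == "prototype" & stim$category == cat][1]
  other <- c(A = "B", B = "A")
  # prototypes within a category share the diagnostic triple and cover both d4
  for (cat in c("A", "B")) {
    ps <- stim[stim$role == "prototype" & stim$category == cat, ]
    if (dist3(ps$id[1], ps$id[2]) != 0L || !setequal(ps$d4, 0:1))
      stop("structural validation: prototype pair malformed in category ", cat,
           call. = FALSE)
  }
  if (dist3(proto("A"), proto("B")) != 3L)
    stop("structural validation: prototypes must differ on all 3 diagnostic dimensions",
         call. = FALSE)
  for (i in seq_len(nrow(stim))) {
    row <- stim[i, ]
    d_own <- dist3(row$id, proto(row$category))
    d_opp <- dist3(row$id, proto(other[[row$category]]))
    ok <- switch(row$role,
      prototype = d_own == 0L,
      rule_follower = d_own == 1L,
      exception = d_own == 2L && d_opp == 1L
    )
    if (!ok)
      stop("structural validation: role-distance invariant violated for ",
           row$id, call. = FALSE)
  }
  invisible(stim)
}

#' Serialize / read a stimulus set as JSON
#'
#' @param stimuli A `stimulus_set`.
#' @param path File path.
#' @return `write_stimulus_set()` returns `path` invisibly;
#'   `read_stimulus_set()` returns a validated `stimulus_set` tibble.
#' @export
write_stimulus_set <- function(stimuli, path) {
  jsonlite::write_json(as.data.frame(stimuli), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(path) {
  df <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  int_cols <- paste0("d", 1:5)
  df[int_cols] <- lapply(df[int_cols], as.integer)
  validate_stimulus_set(df)
  class(df) <- c("stimulus_set", class(df))
  df
}

#' Export the 10 x 10 encoding matrix as plain text
#'
#' Writes the padded binary encodings as a whitespace-separated 0/1 matrix,
#' one stimulus per row in set order.
#'
#' @inheritParams write_stimulus_set
#' @export
write_encoding_matrix <- function(stimuli, path) {
  utils::write.table(encode_stimuli(stimuli), path, row.names = TRUE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
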