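#' Representational similarity matrix of one subfield
#'
#' Pearson correlation between the settled activation vectors of every
#' pair of the 10 stimuli in one hidden layer.  A constant activation
#' vector (possible in an untrained sparse layer) has no defined
#' correlation: its entries are set to `NA` with a warning and excluded
#' from downstream means.
#'
#' @param activations Stimuli x units matrix (rownames = stimulus ids).
#' @return A 10 x 10 symmetric correlation matrix with unit diagonal.
#' @export
rsa_matrix <- function(activations) {
  stopifnot(is.matrix(activations), ncol(activations) >= 2L)
  sds <- apply(activations, 1L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  m <- suppressWarnings(stats::cor(t(activations)))
  if (any(const)) {
    warning(sum(const), " constant activation vector(s): correlations set to NA",
            call. = FALSE)
    m[const, ] <- NA_real_
    m[, const] <- NA_real_
  }
  diag(m) <- ifelse(const, NA_real_, 1)
  m
}

canonical_stimulus_order <- c("PA1", "PA2", "RA1", "RA2", "EA",
                              "PB1", "PB2", "RB1", "RB2", "EB")

as_canonical <- function(matrix) {
  if (is.null(rownames(matrix))) return(matrix)
  if (!setequal(rownames(matrix), canonical_stimulus_order))
    stop("similarity matrix rows do not match the canonical stimulus set",
         call. = FALSE)
  matrix[canonical_stimulus_order, canonical_stimulus_order]
}

#' Early-minus-delayed difference of two similarity matrices
#'
#' @param early,delayed 10 x 10 similarity matrices in the same stimulus
#'   order (checked via rownames when present).
#' @return The elementwise difference `early - delayed`.
#' @export
condition_difference <- function(early, delayed) {
  if (!is.null(rownames(early)) && !is.null(rownames(delayed)) &&
      !identical(rownames(early), rownames(delayed)))
    stop("stimulus order mismatch between condition matrices", call. = FALSE)
  stopifnot(identical(dim(early), dim(delayed)))
  early - delayed
}

#' Mean intercategory similarity of one matrix
#'
#' Mean of the 25 cells pairing a category-A with a category-B stimulus
#' (a per-batch scalar; condition medians are taken across batches
#' downstream).  `NA` cells from constant activation vectors are excluded.
#'
#' @param matrix 10 x 10 similarity matrix in canonical order
#'   (category A then B, each P,P,R,R,E).
#' @return Mean cross-category Pearson correlation.
#' @export
intercategory_similarity <- function(matrix) {
  m <- as_canonical(matrix)
  mean(m[1:5, 6:10], na.rm = TRUE)
}

#' Mean intracategory similarity of one matrix
#'
#' Mean of the 20 off-diagonal within-category cells (10 unordered pairs),
#' the within-category counterpart of [intercategory_similarity()].
#'
#' @inheritParams intercategory_similarity
#' @return Mean within-category Pearson correlation (self excluded).
#' @export
intracategory_similarity <- function(matrix) {
  m <- as_canonical(matrix)
  blocks <- c(m[1:5, 1:5][upper.tri(m[1:5, 1:5])],
              m[6:10, 6:10][upper.tri(m[6:10, 6:10])])
  mean(blocks, na.rm = TRUE)
}

#' Category representational difference (CRD) of an exception
#'
#' The normalized contrast between an exception's mean within-category and
#' between-category representational similarity:
#' `CRD = ((1 + rho_intra) - (1 + rho_inter)) / ((1 + rho_intra) + (1 + rho_inter))`,
#' where `rho_intra` is the exception's mean correlation with the 4 other
#' own-category stimuli (self excluded) and `rho_inter` its mean
#' correlation with the 5 opposite-category stimuli.  Positive CRD means
#' the exception sits representationally inside its own category.
#'
#' @param matrix 10 x 10 similarity matrix in canonical order.
#' @param exception_id `"EA"` or `"EB"`.
#' @return A one-row tibble: `exception_id`, `rho_intra`, `rho_inter`,
#'   `crd`.
#' @export
crd <- function(matrix, exception_id = c("EA", "EB")) {
  exception_id <- match.arg(exception_id)
  m <- as_canonical(matrix)
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- canonical_stimulus_order
  own <- if (exception_id == "EA") canonical_stimulus_order[1:5] else canonical_stimulus_order[6:10]
  opp <- setdiff(canonical_stimulus_order, own)
  rho_intra <- mean(m[exception_id, setdiff(own, exception_id)], na.rm = TRUE)
  rho_inter <- mean(m[exception_id, opp], na.rm = TRUE)
  tibble::tibble(exception_id = exception_id,
                 rho_intra = rho_intra, rho_inter = rho_inter,
                 crd = crd_value(rho_intra, rho_inter))
}

#' CRD from the two mean correlations
#'
#' @param rho_intra,rho_inter Mean intra-/intercategory correlations in
#'   \[-1,1\].
#' @return The normalized difference; errors if both are -1 (zero
#'   denominator).
#' @export
crd_value <- function(rho_intra, rho_inter) {
  num <- (1 + rho_intra) - (1 + rho_inter)
  den <- (1 + rho_intra) + (1 + rho_inter)
  if (any(den <= 0)) stop("degenerate CRD: denominator not positive", call. = FALSE)
  num / den
}

#' Wilcoxon rank-sum comparison of per-batch statistics across conditions
#'
#' Two-sided two-sample rank-sum test with the statistic reported on the
#' standard two-sample W convention, plus both sample medians.
#'
#' @param values_early,values_delayed Per-batch scalar statistics.
#' @return One-row tibble: `statistic_W`, `p_value`, `n_early`,
#'   `n_delayed`, `median_early`, `median_delayed`.
#' @export
ranksum_compare <- function(values_early, values_delayed) {
  stopifnot(length(values_early) > 0L, length(values_delayed) > 0L)
  if (length(unique(c(values_early, values_delayed))) == 1L) {
    warning("all values tied across conditions", call. = FALSE)
    wt <- list(statistic = length(values_early) * length(values_delayed) / 2,
               p.value = 1)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values_early, values_delayed,
                                              exact = FALSE))
  }
  tibble::tibble(
    statistic_W = unname(wt$statistic),
    p_value = wt$p.value,
    n_early = length(values_early),
    n_delayed = length(values_delayed),
    median_early = stats::median(values_early),
    median_delayed = stats::median(values_delayed)
  )
}

#' Per-batch CRD table for an ensemble
#'
#' Computes the CRD of both exceptions in every subfield for every batch
#' at a given checkpoint.
#'
#' @param ensemble An [run_batches()] ensemble.
#' @param checkpoint Trial index (default 144, end of learning).
#' @return Tidy tibble: subfield, condition, exception_id, batch,
#'   rho_intra, rho_inter, crd.
#' @export
crd_table <- function(ensemble, checkpoint = 144L) {
  rsa <- dplyr::filter(ensemble$rsa, .data$checkpoint == !!checkpoint)
  purrr::pmap_dfr(rsa, function(batch, condition, checkpoint, subfield, matrix) {
    dplyr::bind_rows(crd(matrix, "EA"), crd(matrix, "EB")) |>
      dplyr::mutate(subfield = subfield, condition = condition,
                    batch = batch, .before = 1L)
  })
}

#' Ensemble-mean similarity matrix
#'
#' Elementwise mean of the per-batch similarity matrices for one subfield,
#' condition and checkpoint (used for displays and trajectory embeddings;
#' statistics always use the per-batch scalars).
#'
#' @param ensemble An [run_batches()] ensemble.
#' @param subfield `"DG"`, `"CA3"` or `"CA1"`.
#' @param checkpoint Trial index.
#' @return 10 x 10 mean similarity matrix.
#' @export
mean_rsa_matrix <- function(ensemble, subfield, checkpoint) {
  rows <- dplyr::filter(ensemble$rsa, .data$subfield == !!subfield,
                        .data$checkpoint == !!checkpoint)
  if (nrow(rows) == 0L) stop("no matrices for that subfield/checkpoint", call. = FALSE)
  Reduce(`+`, rows$matrix) / length(rows$matrix)
}

#' Write a similarity matrix as CSV with stimulus-id headers
#'
#' @param matrix 10 x 10 similarity matrix.
#' @param path File path.
#' @export
write_rsa_csv <- function(matrix, path) {
  df <- as.data.frame(matrix)
  df <- cbind(stimulus_id = rownames(matrix), df)
  readr::write_csv(df, path)
  invisible(path)
}
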