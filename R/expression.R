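#' Transcripts-per-million normalization
#'
#' TPM for gene g is `1e6 * (count_g / length_g) / sum_h(count_h / length_h)`,
#' computed within each sample (grouping by `sample_id` when present). A
#' sample whose counts are all zero gets all-zero TPM.
#'
#' @param x Data frame with columns `gene_id`, `count`, `length_bp`, and
#'   optionally `sample_id` and `member_id`.
#' @return `x` as a tibble with a `tpm` column added (`count` and `length_bp`
#'   retained).
#' @examples
#' compute_tpm(tibble::tibble(gene_id = c("a", "b"),
#'                            count = c(10, 10), length_bp = c(1000, 2000)))
#' @export
compute_tpm <- function(x) {
  stopifnot(all(c("gene_id", "count", "length_bp") %in% names(x)))
  if (any(is.na(x$length_bp) | x$length_bp <= 0)) {
    stop("every counted gene needs a positive length_bp", call. = FALSE)
  }
  if (any(x$count < 0)) stop("negative counts", call. = FALSE)
  x <- tibble::as_tibble(x)
  if ("sample_id" %in% names(x)) x <- dplyr::group_by(x, .data$sample_id)
  x <- dplyr::mutate(x,
    tpm = {
      rate <- .data$count / .data$length_bp
      tot <- sum(rate)
      if (tot == 0) rep(0, length(rate)) else 1e6 * rate / tot
    })
  dplyr::ungroup(x)
}

#' Read an expression table
#'
#' Tab-separated with columns `sample_id`, `member_id`, `gene_id` and either
#' `tpm` or (`count`, `length_bp`) when `from_counts = TRUE`, in which case
#' TPM is computed per sample via [compute_tpm()].
#'
#' @param path Path to the TSV file.
#' @param from_counts Compute TPM from raw counts and gene lengths.
#' @return Tibble with columns `sample_id`, `member_id`, `gene_id`, `tpm`.
#' @export
read_expression <- function(path, from_counts = FALSE) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "member_id", "gene_id", if (from_counts) c("count", "length_bp") else "tpm")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("expression table lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (from_counts) x <- compute_tpm(x)
  if (any(x$tpm < 0)) stop("negative TPM values", call. = FALSE)
  dplyr::select(x, "sample_id", "member_id", "gene_id", "tpm")
}

#' Reaction-level correction factors from expression via GPR rules
#'
#' For every GPR-bearing reaction of every member, scores the GPR tree against
#' that member's gene expression ([evaluate_gpr()]; genes missing from the
#' table count as 0) and scales by M, the maximum raw score over all members
#' of the community within the sample. Forward/reverse split columns of one
#' reversible reaction share a single factor (one enzyme). Factors are
#' computed independently per sample.
#'
#' @param model A `community_model` (any form; factors key on the reaction,
#'   not the column).
#' @param expression Tibble with columns `sample_id`, `member_id`, `gene_id`,
#'   `tpm` (see [read_expression()]).
#' @return Tibble with one row per (sample, GPR reaction): `sample_id`,
#'   `member_id`, `reaction_id`, `gpr_key`, `f_raw`, `M`, `f_scaled`. Gene ids
#'   present in the expression table but in no GPR are reported in the
#'   `unmatched_genes` attribute.
#' @export
correction_factors <- function(model, expression) {
  stopifnot(inherits(model, "community_model"))
  need <- c("sample_id", "member_id", "gene_id", "tpm")
  stopifnot(all(need %in% names(expression)))
  if (nrow(expression) == 0L) stop("empty expression table", call. = FALSE)
  if (any(expression$tpm < 0)) stop("negative TPM values", call. = FALSE)

  keys <- names(model$gpr)
  if (length(keys) == 0L) stop("model has no GPR-bearing reactions", call. = FALSE)
  key_member <- sub("::.*$", "", keys)
  key_rxn <- sub("^[^:]*::", "", keys)
  model_genes <- unique(unlist(lapply(model$gpr, gpr_genes)))
  unmatched <- sort(setdiff(unique(expression$gene_id), model_genes))

  out <- list()
  for (s in unique(expression$sample_id)) {
    es <- expression[expression$sample_id == s, ]
    f_raw <- numeric(length(keys))
    for (t in seq_along(keys)) {
      em <- es[es$member_id == key_member[t], ]
      theta <- stats::setNames(em$tpm, em$gene_id)
      f_raw[t] <- evaluate_gpr(model$gpr[[keys[t]]], theta)
    }
    M <- max(f_raw)
    if (M <= 0) {
      stop("expression data provide no constraints in sample ", s,
           " (no GPR-bearing reaction has any expressed gene)", call. = FALSE)
    }
    out[[s]] <- tibble::tibble(sample_id = s, member_id = key_member,
                               reaction_id = key_rxn, gpr_key = keys,
                               f_raw = f_raw, M = M, f_scaled = f_raw / M)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "unmatched_genes") <- unmatched
  if (length(unmatched)) {
    message(length(unmatched), " expression gene id(s) match no GPR gene; ",
            "see attr(., 'unmatched_genes')")
  }
  res
}
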