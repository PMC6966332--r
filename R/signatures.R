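# Signature scoring: GMT parsing, TPM normalization and the three scorer
# families (single-gene TPM, rank-z gene-set score, set-ratio score).
#
# The gene-set scorer is a rank-z mean: genes are rank-transformed within
# each sample (average ranks on ties), ranks standardized to mean 0 / sd 1,
# and the score is the mean standardized rank over the up-genes minus the
# mean over the down-genes. It depends on expression only through
# within-sample ranks, so any strictly monotone per-sample transform
# (counts vs TPM, log, ...) leaves scores bit-identical. This is a
# deliberate, exactly testable stand-in for kernel-based single-sample
# enrichment scores such as GSVA: it preserves the sample ordering those
# methods target without their unstated smoothing parameters.

#' Construct a gene signature
#'
#' @param name Identifier for the signature.
#' @param genes_up Character vector of up-regulated member genes.
#' @param genes_down Optional character vector of down-regulated members.
#' @param scoring One of `"single_gene"`, `"rank_set"`, `"set_ratio"`.
#' @param partner For `set_ratio`, the name of the denominator signature.
#'
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes_up, genes_down = NULL,
                           scoring = c("rank_set", "single_gene", "set_ratio"),
                           partner = NULL) {
  scoring <- match.arg(scoring)
  genes_up <- as.character(genes_up)
  if (length(genes_up) == 0) abort("`genes_up` must be non-empty")
  if (anyDuplicated(genes_up)) {
    warn(sprintf("signature '%s': duplicated up-genes deduplicated", name))
    genes_up <- unique(genes_up)
  }
  if (!is.null(genes_down)) {
    genes_down <- unique(as.character(genes_down))
    if (length(intersect(genes_up, genes_down)) > 0)
      abort(sprintf("signature '%s': genes_up and genes_down overlap", name))
  }
  if (scoring == "set_ratio" && is.null(partner))
    abort("set_ratio signatures need a `partner`")
  structure(list(name = name, genes_up = genes_up, genes_down = genes_down,
                 scoring = scoring, partner = partner),
            class = "gene_signature")
}

as_gene_signature <- function(x) {
  if (inherits(x, "gene_signature")) return(x)
  if (is.character(x)) return(gene_signature("signature", x))
  abort("cannot interpret object as a gene signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d up%s [%s]\n", x$name,
              length(x$genes_up),
              if (length(x$genes_down)) sprintf(" / %d down", length(x$genes_down)) else "",
              x$scoring))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One signature per line: name, description, then member genes, all
#' tab-separated. Duplicate gene symbols within a set are dropped with a
#' warning.
#'
#' @param path Path to a GMT file.
#' @return Tibble with columns `name`, `description` and a `genes`
#'   list-column.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(tibble(name = character(), description = character(),
                  genes = list()))
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      abort(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(sprintf("GMT line %d ('%s'): duplicated genes deduplicated",
                   i, fields[[1]]))
      genes <- unique(genes)
    }
    tibble(name = fields[[1]], description = fields[[2]], genes = list(genes))
  })
  dplyr::bind_rows(rows)
}

#' Convert raw counts to transcripts per million (TPM)
#'
#' Per sample: `rate_g = count_g / length_g`, scaled so each sample column
#' sums to one million.
#'
#' @param counts Gene x sample numeric matrix with rownames.
#' @param lengths Named per-gene effective lengths in bases.
#'
#' @return Gene x sample TPM matrix.
#' @export
counts_to_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) abort("`counts` must have gene rownames")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing) > 0)
    abort(paste0("missing gene lengths: ", paste(missing, collapse = ", ")))
  len <- lengths[rownames(counts)]
  if (any(!is.finite(len)) || any(len <= 0))
    abort("gene lengths must be positive and finite")
  rate <- counts / len
  totals <- colSums(rate)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0] %||% which(totals == 0)
    abort(paste0("all-zero sample(s): ", paste(bad, collapse = ", ")))
  }
  sweep(rate, 2, totals, "/") * 1e6
}

#' Single-gene expression score
#'
#' Returns one gene's TPM row, optionally log2(x + 1) transformed (as used
#' before clustering so a few extreme samples do not dominate).
#'
#' @param tpm Gene x sample TPM matrix.
#' @param gene Gene identifier.
#' @param log2p1 Apply `log2(x + 1)`.
#'
#' @return Named per-sample numeric vector.
#' @export
score_single_gene <- function(tpm, gene, log2p1 = FALSE) {
  if (!gene %in% rownames(tpm))
    abort(sprintf("gene '%s' absent from the expression matrix", gene))
  x <- tpm[gene, ]
  if (log2p1) x <- log2(x + 1)
  x
}

# standardized within-sample average ranks (genes x samples)
rank_z_matrix <- function(expr) {
  apply(expr, 2, function(col) {
    r <- rank(col, ties.method = "average")
    (r - mean(r)) / sd(r)
  })
}

#' Rank-z gene-set score
#'
#' @param expr Gene x sample expression matrix (counts or TPM; invariant
#'   to strictly monotone per-sample transforms).
#' @param sig A [gene_signature()] or character vector of up-genes.
#'
#' @return Named per-sample numeric score vector.
#' @export
score_rank_set <- function(expr, sig) {
  sig <- as_gene_signature(sig)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) abort("`expr` must have gene rownames")

  keep_genes <- function(genes, side) {
    present <- intersect(genes, rownames(expr))
    if (length(genes) > 0 && length(present) < length(genes)) {
      missing <- setdiff(genes, present)
      if (length(present) < length(genes) / 2)
        abort(sprintf("signature '%s': over half of the %s genes are missing (%s)",
                      sig$name, side, paste(missing, collapse = ", ")))
      warn(sprintf("signature '%s': dropping missing %s genes: %s",
                   sig$name, side, paste(missing, collapse = ", ")))
    }
    present
  }
  up <- keep_genes(sig$genes_up, "up")
  down <- keep_genes(sig$genes_down %||% character(), "down")
  if (length(up) == 0 && length(down) == 0)
    abort(sprintf("signature '%s': no member gene present", sig$name))

  Z <- rank_z_matrix(expr)
  score <- if (length(up) > 0) colMeans(Z[up, , drop = FALSE]) else 0
  if (length(down) > 0) score <- score - colMeans(Z[down, , drop = FALSE])
  setNames(as.numeric(score), colnames(expr))
}

#' Set-ratio score
#'
#' Contrast of two set scores, by default the difference of the (already
#' standardized) rank-z scores — numerically stable where a literal
#' quotient would divide by near-zero values. A quotient on strictly
#' positive scores is available via `method = "quotient"`.
#'
#' @param score_a,score_b Aligned per-sample score vectors.
#' @param method `"difference"` (default) or `"quotient"`.
#'
#' @return Per-sample ratio score.
#' @export
score_set_ratio <- function(score_a, score_b,
                            method = c("difference", "quotient")) {
  method <- match.arg(method)
  if (length(score_a) != length(score_b))
    abort("score vectors have different lengths")
  na <- names(score_a); nb <- names(score_b)
  if (!is.null(na) && !is.null(nb) && !identical(na, nb))
    abort("score vectors are not aligned on the same samples")
  if (method == "difference") return(score_a - score_b)
  if (any(score_a <= 0) || any(score_b <= 0))
    abort("quotient scoring needs strictly positive scores")
  score_a / score_b
}

#' Score a panel of signatures on an expression matrix
#'
#' Dispatches each signature to its scorer: `single_gene` rows are taken
#' from the TPM matrix (computed from `lengths` when supplied, otherwise
#' `expr` is assumed TPM already), `rank_set` signatures go through
#' [score_rank_set()], and `set_ratio` signatures are computed as the
#' contrast with their partner signature's rank-z score.
#'
#' @param expr Gene x sample matrix (raw counts or TPM).
#' @param signatures List of [gene_signature()] objects.
#' @param lengths Optional named gene lengths enabling TPM conversion for
#'   single-gene scores.
#'
#' @return Tibble, one row per sample: `sample` plus one column per
#'   signature. Attribute `"provenance"` records the scale each score is
#'   on (TPM vs rank score).
#' @export
score_signatures <- function(expr, signatures, lengths = NULL) {
  expr <- as.matrix(expr)
  signatures <- lapply(signatures, as_gene_signature)
  names(signatures) <- vapply(signatures, `[[`, character(1), "name")
  tpm <- if (!is.null(lengths)) counts_to_tpm(expr, lengths) else expr

  base_scores <- list()
  provenance <- character()
  for (s in signatures) {
    if (s$scoring == "single_gene") {
      base_scores[[s$name]] <- score_single_gene(tpm, s$genes_up[[1]])
      provenance[[s$name]] <- "TPM"
    } else if (s$scoring == "rank_set") {
      base_scores[[s$name]] <- score_rank_set(expr, s)
      provenance[[s$name]] <- "rank_z"
    }
  }
  for (s in signatures) {
    if (s$scoring == "set_ratio") {
      num <- score_rank_set(expr, s)
      den <- base_scores[[s$partner]]
      if (is.null(den)) {
        partner_sig <- signatures[[s$partner]]
        if (is.null(partner_sig))
          abort(sprintf("set_ratio partner '%s' not among the signatures", s$partner))
        den <- score_rank_set(expr, partner_sig)
      }
      base_scores[[s$name]] <- score_set_ratio(num, den)
      provenance[[s$name]] <- "rank_z_ratio"
    }
  }
  out <- dplyr::bind_cols(
    tibble(sample = colnames(expr) %||% sprintf("S%03d", seq_len(ncol(expr)))),
    as_tibble(lapply(base_scores[names(signatures)], unname))
  )
  attr(out, "provenance") <- provenance
  out
}

#' Write / read a score matrix as tab-separated text
#'
#' @param scores Samples x markers tibble (first column `sample`).
#' @param path File path.
#' @return `read_scores()` returns a tibble.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(scores, path, na = "")
  invisible(scores)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  readr::read_tsv(path, na = "", show_col_types = FALSE)
}
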