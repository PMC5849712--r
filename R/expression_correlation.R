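#' Per-gene expression as RPKM
#'
#' RPKM = exonic reads x 1e9 / (exonic model length x total mapped reads),
#' computed on the longest gene model only (the model retained by
#' [load_annotation()]).  Only uniquely aligned primary reads enter the
#' exonic counts; no multiread rescue is attempted.  Genes with zero exonic
#' reads get RPKM 0 and are flagged unexpressed.
#'
#' @param evidence a `splice_evidence` (its `exon_counts` and `library`).
#' @param annotation a `splice_annotation`.
#' @return data frame `gene_id`, `exonic_read_count`, `exonic_length_bp`,
#'   `rpkm`, `expressed`.
#' @export
compute_rpkm <- function(evidence, annotation) {
  g <- annotation$genes
  counts <- evidence$exon_counts
  n <- counts$exon_reads[match(g$gene_id, counts$gene_id)]
  n[is.na(n)] <- 0L
  if (any(g$exonic_len <= 0L))
    stop("zero-length exon model for gene ",
         g$gene_id[which(g$exonic_len <= 0L)[1L]])
  total <- evidence$library$total_mapped
  data.frame(
    gene_id = g$gene_id,
    exonic_read_count = n,
    exonic_length_bp = g$exonic_len,
    rpkm = n * 1e9 / (g$exonic_len * total),
    expressed = n >= 1L,
    stringsAsFactors = FALSE)
}

#' Binned trend of AS incidence against a genic feature
#'
#' Bins genes into quantile bins of one feature (expression RPKM, intron or
#' exon number, mean intron or exon length), computes the per-bin proportion
#' of genes carrying at least one qualifying event, and fits an ordinary
#' least-squares line of proportion on bin midpoint.  The slope's two-sided
#' t-test p-value quantifies the trend.
#'
#' @param events event data frame for one species.
#' @param annotation a `splice_annotation`.
#' @param feature one of `"rpkm"`, `"intron_number"`, `"intron_length"`,
#'   `"exon_number"`, `"exon_length"`.
#' @param expression optional output of [compute_rpkm()] (required for
#'   `feature = "rpkm"`; also restricts the gene universe to expressed
#'   genes when given).
#' @param event_type optional filter (e.g. `"IR"`); `NULL` counts any event.
#' @param n_bins number of quantile bins (default 10).
#' @return one-row-per-bin data frame plus attributes `slope`, `r_squared`,
#'   `p_value`; also returned as a list of class `binned_trend`.
#' @export
trend_vs_feature <- function(events, annotation, feature,
                             expression = NULL, event_type = NULL,
                             n_bins = 10L) {
  feature <- match.arg(feature, c("rpkm", "intron_number", "intron_length",
                                  "exon_number", "exon_length"))
  g <- annotation$genes
  ids <- g$gene_id
  value <- switch(feature,
    rpkm = {
      if (is.null(expression)) stop("feature='rpkm' needs expression table")
      expression$rpkm[match(ids, expression$gene_id)]
    },
    intron_number = g$n_exons - 1L,
    exon_number = g$n_exons,
    intron_length = {
      v <- tapply(annotation$introns$end - annotation$introns$start + 1L,
                  annotation$introns$gene_id, mean)
      as.numeric(v[ids])
    },
    exon_length = {
      v <- tapply(annotation$exons$end - annotation$exons$start + 1L,
                  annotation$exons$gene_id, mean)
      as.numeric(v[ids])
    })
  keep <- !is.na(value)
  if (!is.null(expression)) {
    expressed <- expression$gene_id[expression$expressed]
    keep <- keep & ids %in% expressed
  }
  ids <- ids[keep]; value <- value[keep]
  ev <- events
  if (!is.null(event_type)) ev <- ev[ev$event_type %in% event_type, ]
  has_event <- ids %in% unique(ev$gene_id)

  br <- unique(stats::quantile(value, probs = seq(0, 1, length.out =
                                                    n_bins + 1L)))
  if (length(br) < 3L) stop("degenerate binning: all genes in one bin")
  bin <- cut(value, breaks = br, include.lowest = TRUE)
  mid <- (br[-length(br)] + br[-1L]) / 2
  prop <- tapply(has_event, bin, mean)
  n <- tapply(has_event, bin, length)
  tab <- data.frame(bin = levels(bin), midpoint = mid,
                    n_genes = as.integer(n), proportion = as.numeric(prop),
                    stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$proportion), , drop = FALSE]
  if (nrow(tab) < 2L) stop("degenerate binning: fewer than two bins")
  if (stats::var(tab$proportion) == 0) {
    # flat response: no trend by definition
    slope <- 0; r2 <- 0; p <- 1
  } else {
    fit <- stats::lm(proportion ~ midpoint, data = tab)
    sm <- summary(fit)
    slope <- stats::coef(fit)[["midpoint"]]
    r2 <- sm$r.squared
    p <- if (nrow(sm$coefficients) >= 2L) sm$coefficients["midpoint", 4L]
         else NA_real_
  }
  structure(list(feature = feature, bins = tab, slope = slope,
                 r_squared = r2, p_value = p),
            class = "binned_trend")
}

#' @export
print.binned_trend <- function(x, ...) {
  cat("binned_trend of AS proportion vs ", x$feature, ": slope = ",
      signif(x$slope, 4), ", R^2 = ", round(x$r_squared, 3),
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}
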