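# qPCR cycle-threshold arithmetic: delta-Ct relative to a reference
# (housekeeping) gene and delta-delta-Ct relative to a control group.

.check_ct_table <- function(table) {
  need <- c("sample", "gene", "ct")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(table$ct)) || any(table$ct <= 0)) {
    stop("Ct values must be finite and > 0", call. = FALSE)
  }
  invisible(table)
}

#' Per-sample delta-Ct
#'
#' `dCt = Ct(gene) - Ct(reference)` for every (sample, gene), using the
#' per-sample mean reference Ct over replicates. Lower dCt means higher
#' relative expression; the output carries this as an annotation column.
#'
#' @param table Data.frame with columns `sample`, `gene`, `ct` (and
#'   optionally `group`). Replicate rows are averaged per (sample, gene).
#' @param reference Reference (housekeeping) gene name (default
#'   `"MCM2"`, the nanofluidic-panel convention; use `"actin"` for
#'   classical RT-qPCR).
#' @return Data.frame: `sample` (+ `group` if present), `gene`,
#'   `delta_ct`, `relative_expression` (`2^-dCt`, labeled convention).
#' @examples
#' ct <- data.frame(sample = "s1", gene = c("tgt", "MCM2"), ct = c(25, 20))
#' delta_ct(ct)$delta_ct  # 5
#' @export
delta_ct <- function(table, reference = "MCM2") {
  .check_ct_table(table)
  by_cols <- intersect(c("sample", "group", "gene"), names(table))
  agg <- stats::aggregate(table["ct"], table[by_cols], mean)
  ref <- agg[agg$gene == reference, c("sample", "ct")]
  names(ref)[2] <- "ref_ct"
  missing_ref <- setdiff(unique(agg$sample), unique(ref$sample))
  if (length(missing_ref)) {
    stop("reference gene '", reference, "' missing in sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  ref <- stats::aggregate(ref["ref_ct"], ref["sample"], mean)
  out <- merge(agg[agg$gene != reference, , drop = FALSE], ref,
               by = "sample")
  out$delta_ct <- out$ct - out$ref_ct
  out$relative_expression <- 2^(-out$delta_ct)  # convention: lower dCt = higher expression
  out[order(out$sample, out$gene),
      c(intersect(c("sample", "group"), names(out)),
        "gene", "delta_ct", "relative_expression")]
}

#' Delta-delta-Ct and fold change
#'
#' Normalizes each target gene to the reference gene per sample (dCt),
#' then to the mean dCt of the control group per gene:
#' `ddCt = dCt(sample) - mean dCt(control)`; fold change `2^-ddCt` (the
#' standard conversion, emitted alongside raw ddCt as a labeled
#' convention). Genes observed in only one group are skipped with a
#' warning.
#'
#' @param table Data.frame with columns `sample`, `group` (values
#'   `"control"` / `"experimental"`), `gene`, `ct`.
#' @param reference Reference gene (default `"actin"`).
#' @return List: `per_sample` (data.frame with `delta_ct`,
#'   `delta_delta_ct`, `fold_change`), `per_gene` (group means +/- SEM of
#'   ddCt and mean fold change for the experimental group).
#' @examples
#' ct <- data.frame(sample = rep(c("c1", "c2", "e1"), each = 2),
#'                  group = rep(c("control", "control", "experimental"), each = 2),
#'                  gene = rep(c("tgt", "actin"), 3),
#'                  ct = c(25, 20, 25, 20, 26, 20))
#' delta_delta_ct(ct)$per_sample
#' @export
delta_delta_ct <- function(table, reference = "actin") {
  .check_ct_table(table)
  if (!"group" %in% names(table)) {
    stop("ddCt requires a 'group' column (control / experimental)",
         call. = FALSE)
  }
  d <- delta_ct(table, reference = reference)
  keep <- vapply(split(d$group, d$gene),
                 function(g) all(c("control", "experimental") %in% g),
                 TRUE)
  dropped <- names(keep)[!keep]
  if (length(dropped)) {
    warning("gene(s) present in a single group skipped: ",
            paste(dropped, collapse = ", "))
    d <- d[d$gene %in% names(keep)[keep], , drop = FALSE]
  }
  ctrl <- tapply(d$delta_ct[d$group == "control"],
                 d$gene[d$group == "control"], mean)
  d$delta_delta_ct <- as.numeric(d$delta_ct - ctrl[d$gene])
  d$fold_change <- 2^(-d$delta_delta_ct)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  per_gene <- do.call(rbind, lapply(split(d, d$gene), function(g) {
    e <- g[g$group == "experimental", ]
    c0 <- g[g$group == "control", ]
    data.frame(gene = g$gene[1],
               mean_ddct_experimental = mean(e$delta_delta_ct),
               sem_ddct_experimental = sem(e$delta_delta_ct),
               mean_ddct_control = mean(c0$delta_delta_ct),
               sem_ddct_control = sem(c0$delta_delta_ct),
               mean_fold_experimental = mean(e$fold_change))
  }))
  rownames(per_gene) <- NULL
  list(per_sample = d, per_gene = per_gene)
}
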