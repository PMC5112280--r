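# Validation analyses: 5'-RACE cleavage-site mapping onto the miRNA
# complementary region, and 2^-ddCt relative quantification with
# miRNA/target profile correlation.

#' Map 5'-RACE clone ends onto a miRNA complementary region
#'
#' Converts each clone's 5'-end transcript coordinate into a miRNA-relative
#' position: position `p` means the clone end is the target base paired to
#' miRNA base `p` (counted from the miRNA 5' end), so canonical cleavage
#' between miRNA bases 10 and 11 concentrates clones at positions 9-11.
#' Clones outside the site +/- `flank` are tallied as unmapped; fractions
#' are over mapped clones.
#'
#' @param clones data.frame with columns `target_id`, `clone_id`,
#'   `five_prime_pos_1based`.
#' @param target_len length of the target transcript (nt).
#' @param mirna_len miRNA length (nt).
#' @param site a TargetHit row (or list) with `start`/`end`, the 0-based
#'   half-open site coordinates on the transcript.
#' @param flank mapping window beyond the site.
#' @return a CleavageMap: list with `positions` data.frame (`position`,
#'   `count`, `fraction`), `n_mapped`, `n_unmapped`, `canonical_fraction`
#'   (positions 9-11).
#' @export
map_cleavage <- function(clones, target_len, mirna_len, site, flank = 20L) {
  pos1 <- clones$five_prime_pos_1based
  if (any(pos1 < 1L | pos1 > target_len)) {
    stopf("clone 5' end outside transcript (length %d)", target_len)
  }
  t0 <- pos1 - 1L
  p <- site$end - t0                      # miRNA-relative position
  lo <- 1L - flank
  hi <- mirna_len + flank
  mapped <- p >= lo & p <= hi
  tab <- table(p[mapped])
  positions <- data.frame(position = as.integer(names(tab)),
                          count = as.integer(tab))
  positions <- positions[order(positions$position), , drop = FALSE]
  rownames(positions) <- NULL
  n_mapped <- sum(mapped)
  positions$fraction <- if (n_mapped > 0) positions$count / n_mapped else
    numeric(nrow(positions))
  canonical <- if (n_mapped > 0) {
    sum(positions$fraction[positions$position >= 9L &
                             positions$position <= 11L])
  } else {
    NA_real_
  }
  structure(list(positions = positions, n_mapped = n_mapped,
                 n_unmapped = sum(!mapped),
                 canonical_fraction = canonical),
            class = "CleavageMap")
}

#' @export
print.CleavageMap <- function(x, ...) {
  cat(sprintf("CleavageMap: %d mapped / %d unmapped clones, 9-11 fraction %.3f\n",
              x$n_mapped, x$n_unmapped, x$canonical_fraction))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per biological replicate; per
#' replicate, dCt = Ct(gene) - Ct(reference); ddCt subtracts the mean dCt
#' of the calibrator sample; relative expression is `2^-ddCt`, summarized
#' as mean and SD over biological replicates only.
#'
#' @param ct_table data.frame with columns `gene`, `sample`, `bio_rep`,
#'   `tech_rep`, `ct` (a path to such a TSV is also accepted).
#' @param reference_gene internal reference gene present in every sample.
#' @param calibrator_sample sample used as calibrator.
#' @return list: `summary` data.frame (`gene`, `sample`, `rel_expr`,
#'   `sd`, `ddct`), and `replicates` with per-biological-replicate values.
#' @export
ddct <- function(ct_table, reference_gene, calibrator_sample) {
  if (is.character(ct_table) && length(ct_table) == 1L) {
    ct_table <- read.delim(ct_table, stringsAsFactors = FALSE)
  }
  need <- c("gene", "sample", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(ct_table))) {
    stopf("ct_table must have columns: %s", paste(need, collapse = ", "))
  }
  if (!reference_gene %in% ct_table$gene) {
    stopf("reference gene '%s' absent from ct_table", reference_gene)
  }
  # average technical replicates
  bio <- aggregate(ct ~ gene + sample + bio_rep, ct_table, mean)
  ref <- bio[bio$gene == reference_gene, , drop = FALSE]
  tgt <- bio[bio$gene != reference_gene, , drop = FALSE]
  key <- function(d) paste(d$sample, d$bio_rep)
  idx <- match(key(tgt), key(ref))
  if (anyNA(idx)) {
    stopf("missing reference measurements for: %s",
          paste(unique(key(tgt)[is.na(idx)]), collapse = "; "))
  }
  tgt$dct <- tgt$ct - ref$ct[idx]
  if (!calibrator_sample %in% tgt$sample) {
    stopf("calibrator sample '%s' absent", calibrator_sample)
  }
  out <- list()
  for (g in unique(tgt$gene)) {
    sub <- tgt[tgt$gene == g, , drop = FALSE]
    cal <- mean(sub$dct[sub$sample == calibrator_sample])
    sub$ddct <- sub$dct - cal
    sub$rel_expr <- 2^(-sub$ddct)
    out[[g]] <- sub
  }
  reps <- do.call(rbind, out)
  rownames(reps) <- NULL
  summ <- aggregate(cbind(rel_expr, ddct) ~ gene + sample, reps, mean)
  sds <- aggregate(rel_expr ~ gene + sample, reps, sd)
  summ$sd <- sds$rel_expr[match(paste(summ$gene, summ$sample),
                                paste(sds$gene, sds$sample))]
  summ <- summ[order(summ$gene, match(summ$sample, unique(ct_table$sample))),
               c("gene", "sample", "rel_expr", "sd", "ddct")]
  rownames(summ) <- NULL
  list(summary = summ, replicates = reps)
}

#' Correlate a miRNA profile with a target expression profile
#'
#' With only a handful of developmental time points the coefficient is
#' descriptive; no p-value is reported.
#'
#' @param mirna_profile,target_profile equal-length numeric profiles over
#'   the libraries.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list: `r`, `anti_correlated` (`r < 0`), `method`.
#' @export
correlate_profiles <- function(mirna_profile, target_profile,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(mirna_profile) != length(target_profile)) {
    stopf("profiles must have equal length")
  }
  if (sd(mirna_profile) == 0 || sd(target_profile) == 0) {
    stopf("correlation undefined for a zero-variance profile")
  }
  r <- cor(mirna_profile, target_profile, method = method)
  list(r = r, anti_correlated = r < 0, method = method)
}
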