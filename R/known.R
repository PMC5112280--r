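# Assignment of reads to known mature miRNAs (mismatch-tolerant), family
# summaries, and isomiR (sequence/length variant) bookkeeping.

#' Merge collapsed libraries into a sequence-by-library count matrix
#'
#' @param libs list of `ReadLibrary` objects.
#' @param exclude_contaminants drop reads classified to a contaminant class
#'   (requires [classify_contaminants()] to have run).
#' @return integer matrix, rownames = unique sequences (union across
#'   libraries), colnames = library labels.
#' @export
merge_libraries <- function(libs, exclude_contaminants = TRUE) {
  labels <- vapply(libs, function(l) l$label, "")
  if (anyDuplicated(labels)) stopf("duplicate library labels")
  keep <- lapply(libs, function(lib) {
    if (exclude_contaminants && !is.null(lib$annotation_class)) {
      lib$annotation_class == "none"
    } else {
      rep(TRUE, length(lib$sequences))
    }
  })
  seqs <- sort(unique(unlist(
    mapply(function(l, k) l$sequences[k], libs, keep, SIMPLIFY = FALSE))))
  m <- matrix(0L, nrow = length(seqs), ncol = length(libs),
              dimnames = list(seqs, labels))
  for (i in seq_along(libs)) {
    s <- libs[[i]]$sequences[keep[[i]]]
    m[match(s, seqs), i] <- libs[[i]]$counts[keep[[i]]]
  }
  m
}

#' Assign reads to known mature miRNAs
#'
#' Reads are compared to every reference mature of equal length and
#' assigned to the reference(s) with the fewest substitutions, provided at
#' most `max_mismatch`; equal-best ties split the read count evenly so
#' totals are conserved.  Reads 1--2 nt shorter or longer are attached to a
#' call as 3' length variants (isomiRs) when their 5'-anchored overlap is
#' within the mismatch budget; they are flagged, not treated as distinct
#' miRNAs.  Contaminant-classified reads are excluded upstream by
#' [merge_libraries()].
#'
#' @param libs list of `ReadLibrary` objects (ideally contaminant
#'   annotated), or a pre-built count matrix from [merge_libraries()].
#' @param mature_ref named character vector of mature sequences (or FASTA
#'   path with miRBase-style `>family-id` headers).
#' @param max_mismatch substitution budget (no indels).
#' @param length_variant_nt how far a 3' length variant may deviate.
#' @return list with `calls` (list of KnownMiRNACall records: `mirna_id`,
#'   `family`, `canonical`, `variants` data.frame, per-library `totals`)
#'   and `unassigned` (count matrix of reads passed through for novel
#'   prediction).
#' @export
assign_known <- function(libs, mature_ref, max_mismatch = 2L,
                         length_variant_nt = 2L) {
  counts <- if (is.matrix(libs)) libs else merge_libraries(libs)
  if (is.character(mature_ref) && length(mature_ref) == 1L &&
      file.exists(mature_ref)) {
    mature_ref <- read_fasta(mature_ref)
  }
  if (length(mature_ref) == 0L) stopf("mature reference is empty")
  if (anyDuplicated(names(mature_ref))) {
    stopf("duplicate reference IDs in mature reference")
  }
  mature_ref <- vapply(mature_ref, as_dna, "")
  seqs <- rownames(counts)
  ref_len <- nchar(mature_ref)
  read_len <- nchar(seqs)
  # per-read mismatch count against every reference (reads x refs), with
  # width-grouped vectorized comparisons; Inf = incomparable
  mm_equal <- matrix(Inf, nrow = length(seqs), ncol = length(mature_ref),
                     dimnames = list(NULL, names(mature_ref)))
  mm_lenvar <- mm_equal
  char_mat <- function(x, w) {
    matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
           ncol = w, byrow = TRUE)
  }
  for (w in intersect(unique(read_len),
                      seq(min(ref_len) - length_variant_nt,
                          max(ref_len) + length_variant_nt))) {
    idx <- which(read_len == w)
    if (!length(idx)) next
    rm <- char_mat(seqs[idx], w)
    for (r in seq_along(mature_ref)) {
      ov <- min(w, ref_len[r])
      if (abs(ref_len[r] - w) > length_variant_nt &&
          ref_len[r] != w) next
      rr <- strsplit(mature_ref[[r]], "", fixed = TRUE)[[1]][seq_len(ov)]
      mm <- rowSums(rm[, seq_len(ov), drop = FALSE] !=
                      matrix(rr, nrow = length(idx), ncol = ov, byrow = TRUE))
      if (ref_len[r] == w) {
        mm_equal[idx, r] <- mm    # full-length comparison
      } else {
        mm_lenvar[idx, r] <- mm   # 5'-anchored overlap (3' length variant)
      }
    }
  }
  asg <- vector("list", length(seqs))
  best_eq <- apply(mm_equal, 1L, min)
  best_lv <- apply(mm_lenvar, 1L, min)
  for (i in which(pmin(best_eq, best_lv) <= max_mismatch)) {
    if (best_eq[i] <= max_mismatch) {
      sel <- which(mm_equal[i, ] == best_eq[i])
      asg[[i]] <- data.frame(ref = names(mature_ref)[sel],
                             mismatches = best_eq[i],
                             length_variant = FALSE)
    } else {
      sel <- which(mm_lenvar[i, ] == best_lv[i])
      asg[[i]] <- data.frame(ref = names(mature_ref)[sel],
                             mismatches = best_lv[i],
                             length_variant = TRUE)
    }
  }
  assigned <- !vapply(asg, is.null, TRUE)
  calls <- list()
  for (id in names(mature_ref)) {
    rows <- which(vapply(asg, function(a) !is.null(a) && id %in% a$ref, TRUE))
    if (length(rows) == 0L) next
    vr <- do.call(rbind, lapply(rows, function(i) {
      a <- asg[[i]]
      share <- 1 / nrow(a)
      cnts <- setNames(as.numeric(counts[i, ]) * share, colnames(counts))
      do.call(data.frame, c(
        list(sequence = seqs[i],
             mismatches = a$mismatches[a$ref == id][1],
             length_variant = a$length_variant[a$ref == id][1],
             share = share),
        as.list(cnts), list(check.names = FALSE)))
    }))
    rownames(vr) <- NULL
    totals <- colSums(vr[, colnames(counts), drop = FALSE])
    calls[[id]] <- structure(list(
      mirna_id = id,
      family = parse_mirna_family(id),
      canonical = unname(mature_ref[[id]]),
      variants = vr,
      totals = totals
    ), class = "KnownMiRNACall")
  }
  list(calls = calls,
       unassigned = counts[!assigned, , drop = FALSE])
}

#' @export
print.KnownMiRNACall <- function(x, ...) {
  cat(sprintf("%s (%s): %d variant sequence(s), totals %s\n", x$mirna_id,
              x$family, nrow(x$variants),
              paste(sprintf("%s=%.1f", names(x$totals), x$totals),
                    collapse = " ")))
  invisible(x)
}

#' Parse a miRNA family name from a reference identifier
#'
#' Extracts the canonical `miR<number>` token (case-insensitive, optional
#' species prefix and member suffix), e.g. `"gar-miR156a-2"` -> `"miR156"`.
#'
#' @param id character vector of reference identifiers.
#' @return character vector of family names; identifiers without a
#'   recognizable token are returned unchanged.
#' @export
parse_mirna_family <- function(id) {
  m <- regmatches(id, regexpr("[Mm][Ii][Rr][0-9]+", id))
  out <- id
  hit <- regexpr("[Mm][Ii][Rr][0-9]+", id) > 0L
  out[hit] <- paste0("miR", sub("^[Mm][Ii][Rr]", "", m))
  out
}

#' Family membership summary of known-miRNA calls
#'
#' Members of a family are counted as distinct canonical sequences (or
#' distinct reference entries where canonicals coincide).
#'
#' @param calls list of `KnownMiRNACall` records (from
#'   [assign_known()]`$calls`).
#' @return data.frame `family`, `members`, ordered by family name.
#' @export
family_summary <- function(calls) {
  if (length(calls) == 0L) {
    return(data.frame(family = character(0), members = integer(0)))
  }
  fam <- vapply(calls, function(c) c$family, "")
  key <- paste(fam, vapply(calls, function(c) c$canonical, ""),
               vapply(calls, function(c) c$mirna_id, ""))
  df <- unique(data.frame(family = fam, key = key))
  out <- aggregate(key ~ family, df, length)
  names(out) <- c("family", "members")
  out <- out[order(out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}
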