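# miRNA target prediction: position-weighted complementarity "expectation"
# scoring of miRNA:mRNA duplexes, in the style of the classical plant
# target-prediction servers (match 0, G:U 0.5, mismatch 1, gap 2, all
# doubled in the seed region, cutoff 3).

#' Penalty scheme for miRNA:target duplex scoring
#'
#' @param match,gu,mismatch,gap per-position penalties.
#' @param seed_start,seed_end seed region, miRNA positions counted from the
#'   5' end (inclusive).
#' @param seed_multiplier factor applied to every penalty inside the seed.
#' @return named list describing the scheme.
#' @export
duplex_scheme <- function(match = 0, gu = 0.5, mismatch = 1, gap = 2,
                          seed_start = 2L, seed_end = 13L,
                          seed_multiplier = 2) {
  list(match = match, gu = gu, mismatch = mismatch, gap = gap,
       seed_start = seed_start, seed_end = seed_end,
       seed_multiplier = seed_multiplier)
}

pair_state_chr <- function(mir, tgt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ifelse(mir == "-" | tgt == "-", "gap",
  ifelse(comp[mir] == tgt, "match",
  ifelse((mir == "G" & tgt == "T") | (mir == "T" & tgt == "G"), "GU",
         "mismatch")))
}

#' Score a miRNA:target-site duplex
#'
#' Aligns the miRNA (5'->3') antiparallel against the site (given 5'->3' on
#' the transcript): miRNA position 1 pairs the 3'-most site base.  With
#' gap-free input the sequences must have equal length; pre-aligned strings
#' may carry `-` characters.  Positions are indexed from the miRNA 5' end
#' for the seed-region doubling.
#'
#' @param mirna_seq miRNA sequence 5'->3'.
#' @param site_seq target site 5'->3' (transcript orientation).
#' @param scheme from [duplex_scheme()].
#' @return list: `expectation`, `states` (per-position
#'   match/GU/mismatch/gap from the miRNA 5' end), `aln_mirna`, `aln_site`
#'   (site shown 3'->5', aligned under the miRNA).
#' @examples
#' score_duplex("TGGAGAAGCAGGGCACGTGCA",
#'              revcomp("TGGAGAAGCAGGGCACGTGCA"))$expectation  # 0
#' @export
score_duplex <- function(mirna_seq, site_seq, scheme = duplex_scheme()) {
  mir <- strsplit(as_dna(mirna_seq), "", fixed = TRUE)[[1]]
  site <- rev(strsplit(as_dna(site_seq), "", fixed = TRUE)[[1]])
  if (any(!(mir %in% c("A", "C", "G", "T", "-"))) ||
      any(!(site %in% c("A", "C", "G", "T", "-")))) {
    stopf("non-nucleotide characters in duplex input")
  }
  if (length(mir) != length(site)) {
    stopf("gap-free duplex scoring requires equal lengths (got %d and %d)",
          length(mir), length(site))
  }
  states <- pair_state_chr(mir, site)
  # seed position = number of miRNA bases consumed (a gap in the miRNA is
  # charged at the position of the next miRNA base)
  mirpos <- cumsum(mir != "-")
  mirpos[mir == "-"] <- mirpos[mir == "-"] + 1L
  pen <- c(match = scheme$match, GU = scheme$gu, mismatch = scheme$mismatch,
           gap = scheme$gap)[states]
  in_seed <- mirpos >= scheme$seed_start & mirpos <= scheme$seed_end
  pen[in_seed] <- pen[in_seed] * scheme$seed_multiplier
  list(expectation = sum(pen), states = unname(states),
       aln_mirna = paste(mir, collapse = ""),
       aln_site = paste(site, collapse = ""))
}

#' Scan transcripts for miRNA target sites
#'
#' Aligns each miRNA against every transcript window (at most one gap by
#' default) minimizing the expectation penalty, reports hits at or below
#' `max_expectation`, and deduplicates overlapping hits on a transcript
#' keeping the lowest expectation.  Output order is deterministic
#' (miRNA, transcript, position).
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts named character vector (or FASTA path).
#' @param max_expectation reporting cutoff.
#' @param scheme from [duplex_scheme()].
#' @param max_gaps 0 or 1 gaps allowed per duplex.
#' @return data.frame of TargetHit rows: `mirna_id`, `transcript_id`,
#'   `expectation`, `start`, `end` (0-based half-open site coordinates),
#'   `gaps`, `aln_mirna`, `aln_site`, `states`.
#' @export
scan_transcripts <- function(mirnas, transcripts, max_expectation = 3,
                             scheme = duplex_scheme(), max_gaps = 1L) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts)) {
    transcripts <- read_fasta(transcripts)
  }
  if (is.null(names(mirnas)) || is.null(names(transcripts))) {
    stopf("mirnas and transcripts must be named")
  }
  out <- list()
  for (mi in names(mirnas)) {
    mseq <- as_dna(mirnas[[mi]])
    for (ti in names(transcripts)) {
      h <- scan_duplex_cpp(mseq, as_dna(transcripts[[ti]]),
                           scheme$match, scheme$gu, scheme$mismatch,
                           scheme$gap, scheme$seed_start, scheme$seed_end,
                           scheme$seed_multiplier, as.integer(max_gaps),
                           max_expectation)
      if (nrow(h) == 0L) next
      # deduplicate overlapping windows: best expectation, then leftmost
      h <- h[order(h$expectation, h$start, h$gaps), , drop = FALSE]
      kept <- logical(0)
      ks <- integer(0)
      ke <- integer(0)
      sel <- integer(0)
      for (r in seq_len(nrow(h))) {
        if (!any(h$start[r] < ke & h$end[r] > ks)) {
          sel <- c(sel, r)
          ks <- c(ks, h$start[r])
          ke <- c(ke, h$end[r])
        }
      }
      h <- h[sel, , drop = FALSE]
      h$mirna_id <- mi
      h$transcript_id <- ti
      out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0L) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      expectation = numeric(0), start = integer(0),
                      end = integer(0), gaps = integer(0),
                      aln_mirna = character(0), aln_site = character(0),
                      states = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mirna_id, res$transcript_id, res$start),
             c("mirna_id", "transcript_id", "expectation", "start", "end",
               "gaps", "aln_mirna", "aln_site", "states")]
  rownames(res) <- NULL
  res
}

#' Summarize target predictions per miRNA
#'
#' @param hits TargetHit data.frame from [scan_transcripts()].
#' @param mirna_ids optional universe of miRNA identifiers, used to report
#'   miRNAs without any predicted target.
#' @return list: `per_mirna` (data.frame `mirna_id`, `n_targets`),
#'   `n_nonredundant_pairs` (distinct miRNA-transcript pairs),
#'   `n_transcripts` (distinct transcripts), `mean_targets_per_mirna`
#'   (pairs over miRNAs with >= 1 hit, one decimal, half-up), `no_target`
#'   (miRNAs with zero hits).
#' @export
target_summary <- function(hits, mirna_ids = NULL) {
  pairs <- unique(hits[, c("mirna_id", "transcript_id"), drop = FALSE])
  per <- if (nrow(pairs)) {
    as.data.frame(table(mirna_id = pairs$mirna_id),
                  responseName = "n_targets", stringsAsFactors = FALSE)
  } else {
    data.frame(mirna_id = character(0), n_targets = integer(0))
  }
  n_with <- nrow(per)
  mean_t <- if (n_with > 0) {
    round_half_up(nrow(pairs) / n_with, 1)
  } else {
    0.0
  }
  no_target <- if (is.null(mirna_ids)) character(0) else
    setdiff(mirna_ids, per$mirna_id)
  list(per_mirna = per,
       n_nonredundant_pairs = nrow(pairs),
       n_transcripts = length(unique(pairs$transcript_id)),
       mean_targets_per_mirna = mean_t,
       no_target = sort(no_target))
}
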