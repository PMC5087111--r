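#' Pair-assignment parameters
#'
#' Mirrors the contractual semantics of short-read pair mapping against
#' single-cell genomes: exact-seed candidate discovery, ungapped
#' mismatch-counting extension, forward-reverse orientation, inferred
#' fragment length (outer distance) within `[min_frag, max_frag]`, and a
#' pair reported `unique` only when exactly one best-scoring placement
#' exists (ties are `multi` and discarded downstream, never broken randomly).
#'
#' @param seed_k exact-match seed length (>= 8)
#' @param max_mismatch maximum substitutions tolerated per mate
#' @param min_frag,max_frag inferred fragment length bounds (defaults 20/450)
#' @param require_unique keep only single-best placements (default TRUE)
#' @return list of class `sagscope_assign_params`
#' @export
assign_params <- function(seed_k = 15L, max_mismatch = 2L,
                          min_frag = 20L, max_frag = 450L,
                          require_unique = TRUE) {
  stopifnot(seed_k >= 8, min_frag <= max_frag, max_mismatch >= 0)
  structure(list(seed_k = as.integer(seed_k),
                 max_mismatch = as.integer(max_mismatch),
                 min_frag = as.integer(min_frag),
                 max_frag = as.integer(max_frag),
                 require_unique = isTRUE(require_unique)),
            class = "sagscope_assign_params")
}

#' Build an exact-match seed index over a reference set
#'
#' Indexes every forward-strand k-mer position of every contig in a keyed
#' table; reverse-complement queries are handled at query time by seeding
#' with the reverse-complemented read. Index content is a set: independent of
#' contig insertion order.
#'
#' @param refset a [refset()]
#' @param seed_k k-mer length
#' @return object of class `sagscope_index`
#' @export
build_index <- function(refset, seed_k = 15L) {
  seed_k <- as.integer(seed_k)
  seqs <- as.character(refset$contigs)
  tabs <- lapply(sort(names(seqs)), function(cid) {
    s <- seqs[[cid]]
    n <- nchar(s)
    if (n < seed_k) return(NULL)
    p <- seq_len(n - seed_k + 1L)
    data.table::data.table(kmer = substring(s, p, p + seed_k - 1L),
                           contig_id = cid, pos = p - 1L)
  })
  km <- data.table::rbindlist(tabs)
  if (nrow(km)) data.table::setkey(km, kmer)
  structure(
    list(kmers = km, k = seed_k,
         contig_seq = seqs,
         contig_len = stats::setNames(nchar(seqs), names(seqs)),
         contig_genome = stats::setNames(refset$contig_info$genome_id,
                                         refset$contig_info$contig_id)),
    class = "sagscope_index"
  )
}

#' Look up the reference positions of one k-mer
#' @param index a [build_index()] result
#' @param kmer character k-mer of length `index$k`
#' @return tibble of `contig_id`, `pos` (0-based); empty when absent
#' @export
query_index <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$k)
  if (nrow(index$kmers) == 0) {
    return(tibble::tibble(contig_id = character(), pos = integer()))
  }
  # build the lookup table outside the join to avoid self-join name capture
  probe <- data.table::data.table(kmer = kmer)
  hit <- index$kmers[probe, nomatch = NULL]
  tibble::as_tibble(hit[, list(contig_id, pos)])
}

# Non-overlapping seed offsets covering a read of length `len`; the final
# window is anchored to the read end so the whole read is seed-covered.
#' @keywords internal
seed_offsets <- function(len, k) {
  if (len < k) return(integer(0))
  unique(c(seq(0L, len - k, by = k), len - k))
}

#' Assign read pairs to reference loci by seed-and-extend
#'
#' Candidate loci are found by exact seed match (all non-overlapping seed
#' windows of each mate, both orientations), extended ungapped over the full
#' mate while counting mismatches, and paired under forward-reverse
#' orientation with the inferred fragment length (outer distance, SAM TLEN
#' magnitude) within bounds. Pair status is `unique` (exactly one
#' best-scoring in-bounds placement), `multi` (tied best placements),
#' `frag_out_of_bounds` (placements exist, all violating the bounds) or
#' `unmapped`. Deterministic.
#'
#' @param pairs QC-processed pair tibble (see [qc_pairs()])
#' @param index a [build_index()] result
#' @param params an [assign_params()]; `params$seed_k` must equal `index$k`
#' @return assignment tibble: `fragment_id`, `status`, `genome_id`,
#'   `contig_id`, mate intervals (`m1_start`..`m2_end`, 0-based half-open),
#'   `strand` (of mate 1), `n_mismatch`, `frag_len`; coordinate columns are
#'   `NA` unless status is `unique`
#' @export
assign_pairs <- function(pairs, index, params = assign_params()) {
  if (params$seed_k != index$k) {
    stop("params$seed_k does not match the index k")
  }
  n <- nrow(pairs)
  out <- empty_assignment_table(pairs$fragment_id)
  if (n == 0) return(out)

  cands <- find_candidates(pairs, index, params)
  if (nrow(cands) == 0) return(out)

  placed <- pair_candidates(cands, params)
  if (is.null(placed) || nrow(placed) == 0) return(out)

  # classify per pair
  data.table::setDT(placed)
  placed[, score := nm1 + nm2]
  verdict <- placed[, {
    inb <- frag_len >= params$min_frag & frag_len <= params$max_frag
    if (!any(inb)) {
      list(status = "frag_out_of_bounds", contig_id = NA_character_,
           m1_start = NA_integer_, m1_end = NA_integer_,
           m2_start = NA_integer_, m2_end = NA_integer_,
           strand = NA_character_, n_mismatch = NA_integer_,
           frag_len = NA_integer_)
    } else {
      sub <- .SD[inb]
      best <- min(sub$score)
      hits <- sub[score == best]
      if (nrow(hits) > 1L && params$require_unique) {
        list(status = "multi", contig_id = NA_character_,
             m1_start = NA_integer_, m1_end = NA_integer_,
             m2_start = NA_integer_, m2_end = NA_integer_,
             strand = NA_character_, n_mismatch = NA_integer_,
             frag_len = NA_integer_)
      } else {
        h <- hits[1L]
        list(status = "unique", contig_id = h$contig_id,
             m1_start = h$start1, m1_end = h$end1,
             m2_start = h$start2, m2_end = h$end2,
             strand = h$strand1, n_mismatch = h$score,
             frag_len = h$frag_len)
      }
    }
  }, by = pair_id]

  i <- verdict$pair_id
  out$status[i] <- verdict$status
  out$contig_id[i] <- verdict$contig_id
  out$genome_id[i] <- ifelse(is.na(verdict$contig_id), NA_character_,
                             index$contig_genome[verdict$contig_id])
  out$m1_start[i] <- verdict$m1_start; out$m1_end[i] <- verdict$m1_end
  out$m2_start[i] <- verdict$m2_start; out$m2_end[i] <- verdict$m2_end
  out$strand[i] <- verdict$strand
  out$n_mismatch[i] <- verdict$n_mismatch
  out$frag_len[i] <- verdict$frag_len
  out
}

#' @keywords internal
empty_assignment_table <- function(fragment_id) {
  n <- length(fragment_id)
  tibble::tibble(
    fragment_id = fragment_id,
    status = rep("unmapped", n),
    genome_id = rep(NA_character_, n),
    contig_id = rep(NA_character_, n),
    m1_start = rep(NA_integer_, n), m1_end = rep(NA_integer_, n),
    m2_start = rep(NA_integer_, n), m2_end = rep(NA_integer_, n),
    strand = rep(NA_character_, n),
    n_mismatch = rep(NA_integer_, n),
    frag_len = rep(NA_integer_, n)
  )
}

# Seed both mates in both orientations, join against the index, extend
# ungapped and keep candidates within the mismatch budget. Returns one row
# per (pair, mate, orientation, locus).
#' @keywords internal
find_candidates <- function(pairs, index, params) {
  k <- index$k
  reads <- data.table::data.table(
    pair_id = rep(seq_len(nrow(pairs)), 2L),
    mate = rep(1:2, each = nrow(pairs)),
    seq = c(pairs$mate1_seq, pairs$mate2_seq)
  )
  reads[, len := nchar(seq)]
  reads <- reads[len >= k]
  if (nrow(reads) == 0 || nrow(index$kmers) == 0) {
    return(data.table::data.table())
  }
  # orientation "+": mate aligns to the forward contig strand as-is;
  # "-": the reverse-complemented mate aligns forward
  both <- data.table::rbindlist(list(
    data.table::copy(reads)[, `:=`(qstrand = "+", seq_q = seq)],
    data.table::copy(reads)[, `:=`(qstrand = "-", seq_q = revcomp_chr(seq))]
  ))
  offs <- lapply(both$len, seed_offsets, k = k)
  noff <- lengths(offs)
  seeds <- both[rep(seq_len(nrow(both)), noff)]
  seeds[, off := unlist(offs)]
  seeds[, kmer := substring(seq_q, off + 1L, off + k)]
  hits <- index$kmers[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(data.table::data.table())
  hits[, cand_start := pos - off]
  hits <- hits[cand_start >= 0L &
                 cand_start + len <= index$contig_len[contig_id]]
  cands <- unique(hits[, list(pair_id, mate, qstrand, seq_q, len,
                              contig_id, cand_start)])
  if (nrow(cands) == 0) return(cands)
  cands[, refseq := substring(index$contig_seq[contig_id], cand_start + 1L,
                              cand_start + len)]
  cands[, nm := count_mismatches(seq_q, refseq)]
  cands <- cands[nm <= params$max_mismatch]
  cands[, `:=`(seq_q = NULL, refseq = NULL)]
  cands[, cand_end := cand_start + len]
  cands
}

# Combine mate-1 and mate-2 candidates on the same contig with opposite
# orientations into proper forward-reverse pairings; fragment length is the
# outer distance. The forward mate must start at or left of the reverse mate
# (overlapping/short-insert mates allowed).
#' @keywords internal
pair_candidates <- function(cands, params) {
  c1 <- cands[mate == 1L]
  c2 <- cands[mate == 2L]
  if (nrow(c1) == 0 || nrow(c2) == 0) return(NULL)
  data.table::setnames(c1, c("qstrand", "cand_start", "cand_end", "nm"),
                       c("strand1", "start1", "end1", "nm1"))
  data.table::setnames(c2, c("qstrand", "cand_start", "cand_end", "nm"),
                       c("strand2", "start2", "end2", "nm2"))
  m <- merge(c1[, list(pair_id, contig_id, strand1, start1, end1, nm1)],
             c2[, list(pair_id, contig_id, strand2, start2, end2, nm2)],
             by = c("pair_id", "contig_id"), allow.cartesian = TRUE)
  m <- m[strand1 != strand2]
  if (nrow(m) == 0) return(NULL)
  fwd_start <- ifelse(m$strand1 == "+", m$start1, m$start2)
  rev_start <- ifelse(m$strand1 == "+", m$start2, m$start1)
  fwd_end <- ifelse(m$strand1 == "+", m$end1, m$end2)
  rev_end <- ifelse(m$strand1 == "+", m$end2, m$end1)
  ok <- fwd_start <= rev_start & fwd_end <= rev_end
  m <- m[ok]
  if (nrow(m) == 0) return(NULL)
  m[, frag_len := pmax(end1, end2) - pmin(start1, start2)]
  m
}

#' Exhaustive all-positions alignment oracle
#'
#' Reference implementation of pair assignment for small references
#' (independent of the seed index): every mate is aligned at every position
#' of every contig in both orientations by direct mismatch counting, then
#' paired under the same orientation/bounds/uniqueness rules. Intended for
#' validating [assign_pairs()] on instances of a few kb.
#'
#' @inheritParams assign_pairs
#' @param refset a [refset()]
#' @return assignment tibble in the [assign_pairs()] layout
#' @export
align_bruteforce <- function(pairs, refset, params = assign_params()) {
  seqs <- as.character(refset$contigs)
  gmap <- stats::setNames(refset$contig_info$genome_id,
                          refset$contig_info$contig_id)
  out <- empty_assignment_table(pairs$fragment_id)
  locate <- function(read) {
    hits <- list()
    for (cid in names(seqs)) {
      s <- seqs[[cid]]
      L <- nchar(s)
      l <- nchar(read)
      if (l == 0 || l > L) next
      for (st in c("+", "-")) {
        q <- if (st == "+") read else revcomp_chr(read)
        qr <- charToRaw(q)
        for (p in 0:(L - l)) {
          nm <- sum(charToRaw(substring(s, p + 1L, p + l)) != qr)
          if (nm <= params$max_mismatch) {
            hits[[length(hits) + 1L]] <- list(contig = cid, start = p,
                                              end = p + l, strand = st,
                                              nm = nm)
          }
        }
      }
    }
    hits
  }
  for (i in seq_len(nrow(pairs))) {
    h1 <- locate(pairs$mate1_seq[i])
    h2 <- locate(pairs$mate2_seq[i])
    placements <- list()
    for (a in h1) for (b in h2) {
      if (a$contig != b$contig || a$strand == b$strand) next
      fwd <- if (a$strand == "+") a else b
      rev <- if (a$strand == "+") b else a
      if (!(fwd$start <= rev$start && fwd$end <= rev$end)) next
      placements[[length(placements) + 1L]] <- list(
        a = a, b = b, frag = max(a$end, b$end) - min(a$start, b$start),
        score = a$nm + b$nm
      )
    }
    if (length(placements) == 0) next
    frags <- vapply(placements, `[[`, 0, "frag")
    inb <- frags >= params$min_frag & frags <= params$max_frag
    if (!any(inb)) {
      out$status[i] <- "frag_out_of_bounds"
      next
    }
    placements <- placements[inb]
    scores <- vapply(placements, `[[`, 0, "score")
    bests <- which(scores == min(scores))
    if (length(bests) > 1L && params$require_unique) {
      out$status[i] <- "multi"
      next
    }
    p <- placements[[bests[1L]]]
    out$status[i] <- "unique"
    out$contig_id[i] <- p$a$contig
    out$genome_id[i] <- gmap[[p$a$contig]]
    out$m1_start[i] <- p$a$start; out$m1_end[i] <- p$a$end
    out$m2_start[i] <- p$b$start; out$m2_end[i] <- p$b$end
    out$strand[i] <- p$a$strand
    out$n_mismatch[i] <- p$score
    out$frag_len[i] <- p$frag
  }
  out
}
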