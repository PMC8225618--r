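# Independent oracles used by the property tests. These deliberately do
# not share code with the package implementation.

# Decode a CIGAR string with a regex (no GenomicAlignments).
oracle_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

# Project every aligned (M/=/X) base of a read onto reference
# coordinates, and collect the reference intervals skipped by N ops.
oracle_projection <- function(pos, cigar) {
  cg <- oracle_cigar(cigar)
  aligned <- integer()
  skips <- list()
  cur <- pos
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      aligned <- c(aligned, cur:(cur + len - 1L))
      cur <- cur + len
    } else if (op == "N") {
      skips[[length(skips) + 1L]] <- c(cur, cur + len - 1L)
      cur <- cur + len
    } else if (op == "D") {
      cur <- cur + len
    } # I, S, H, P consume no reference
  }
  list(aligned = aligned, skips = skips)
}

# Brute-force junction test: some N skip equals [donor_end+1,
# acceptor_start-1] and the min_overhang reference bases immediately
# left/right of the skip are all aligned.
oracle_spans <- function(chrom, pos, cigar, sig, min_overhang) {
  if (chrom != sig$chrom) return(FALSE)
  pr <- oracle_projection(pos, cigar)
  want <- c(sig$donor_end + 1, sig$acceptor_start - 1)
  for (sk in pr$skips) {
    if (all(sk == want)) {
      left <- (sig$donor_end - min_overhang + 1L):sig$donor_end
      right <- sig$acceptor_start:(sig$acceptor_start + min_overhang - 1L)
      if (all(left %in% pr$aligned) && all(right %in% pr$aligned)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

oracle_count <- function(reads, model, min_overhang) {
  sig <- model$signatures
  counts <- setNames(integer(nrow(sig)), sig$transcript_id)
  for (r in seq_len(nrow(reads))) {
    for (s in seq_len(nrow(sig))) {
      if (oracle_spans(reads$chrom[r], reads$pos[r], reads$cigar[r],
                       sig[s, ], min_overhang)) {
        counts[s] <- counts[s] + 1L
        break
      }
    }
  }
  counts
}

# Two-sided Fisher tail sum straight from dhyper over the full support.
oracle_fisher <- function(a, b, cc, d) {
  N <- a + b + cc + d
  r1 <- a + b; c1 <- a + cc
  support <- max(0L, r1 + c1 - N):min(r1, c1)
  p <- dhyper(support, c1, N - c1, r1)
  p_obs <- dhyper(a, c1, N - c1, r1)
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Exact two-sided Mann-Whitney p by enumerating group assignments.
oracle_mw <- function(x, y) {
  nx <- length(x); N <- nx + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  us <- apply(combn(N, nx), 2, function(ix) {
    sum(r[ix]) - nx * (nx + 1) / 2
  })
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# One SAM line with sensible defaults, for hand-built fixtures.
sam_line <- function(id, flag, chrom, pos, cigar, mapq = 60L) {
  paste(id, flag, chrom, pos, mapq, cigar, "*", 0L, 0L, "A", "I",
        sep = "\t")
}

sam_header <- function(chrom = "chrT_AR", len = 3000L) {
  c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", chrom, len))
}
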