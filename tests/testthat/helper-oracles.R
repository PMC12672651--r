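# Independent oracles and fixture builders.  These deliberately do NOT reuse
# package internals: the pileup oracle expands CIGARs character by character,
# and the detection oracle re-implements the calling rules as plain loops.

# Brute-force pileup recount from an alignment table.  Expands each CIGAR
# into one op letter per consumed unit and walks it with scalar loops.
oracle_pileup <- function(aln, ref) {
  L <- ref$length
  counts <- matrix(0L, nrow = L, ncol = 5,
                   dimnames = list(NULL, c("A", "C", "G", "U", "del")))
  for (i in seq_len(nrow(aln))) {
    cig <- aln$cigar[i]
    lens <- as.integer(strsplit(gsub("[MIDNSHP=X]", " ", cig), " ")[[1]])
    ops <- strsplit(gsub("[0-9]", "", cig), "")[[1]]
    flat <- unlist(mapply(rep, ops, lens, SIMPLIFY = FALSE), use.names = FALSE)
    rp <- aln$pos[i]
    qp <- 1L
    seqv <- strsplit(chartr("T", "U", aln$seq[i]), "")[[1]]
    for (op in flat) {
      if (op %in% c("M", "=", "X")) {
        b <- seqv[qp]
        if (b %in% c("A", "C", "G", "U"))
          counts[rp, b] <- counts[rp, b] + 1L
        rp <- rp + 1L; qp <- qp + 1L
      } else if (op == "D") {
        counts[rp, "del"] <- counts[rp, "del"] + 1L
        rp <- rp + 1L
      } else if (op %in% c("I", "S")) {
        qp <- qp + 1L
      } else if (op == "N") {
        rp <- rp + 1L
      }
    }
  }
  data.frame(position = seq_len(L), nA = counts[, 1], nC = counts[, 2],
             nG = counts[, 3], nU = counts[, 4], nDel = counts[, 5])
}

# Exhaustive re-implementation of the detection rules over a toy table of
# native/IVT counts.  Inputs: data.frame with ref_base, nA..nU per sample.
oracle_detect <- function(native, ivt, threshold = 10, min_depth = 50,
                          neighbor_window = 1, neighbor_floor = 5,
                          psi_dominance = 0.5, external_support = integer()) {
  bases <- c("A", "C", "G", "U")
  err_of <- function(row, ref) {
    cnt <- as.numeric(row[paste0("n", bases)])
    names(cnt) <- bases
    tot <- sum(cnt)
    if (tot == 0) return(list(err = 0, dom = NA_character_))
    nonref <- cnt[setdiff(bases, ref)]
    best <- names(nonref)[which.max(nonref)]  # which.max: first of ties, A<C<G<U
    if (max(nonref) == 0) best <- NA_character_
    list(err = 100 * max(nonref) / tot, dom = best, cnt = cnt)
  }
  n <- nrow(native)
  out <- data.frame(position = native$position, delta = NA_real_,
                    called = FALSE, signature = NA_character_,
                    neighbor = FALSE)
  errs_n <- errs_i <- numeric(n)
  for (i in seq_len(n)) {
    en <- err_of(native[i, ], native$ref_base[i])
    ei <- err_of(ivt[i, ], native$ref_base[i])
    errs_n[i] <- en$err; errs_i[i] <- ei$err
    out$delta[i] <- en$err - ei$err
    dn <- sum(as.numeric(native[i, paste0("n", bases)]))
    di <- sum(as.numeric(ivt[i, paste0("n", bases)]))
    if (out$delta[i] > threshold && dn >= min_depth && di >= min_depth) {
      out$called[i] <- TRUE
      cnt <- as.numeric(native[i, paste0("n", bases)]); names(cnt) <- bases
      nonref_tot <- sum(cnt) - cnt[native$ref_base[i]]
      is_psi <- native$ref_base[i] == "U" && identical(en$dom, "C") &&
        nonref_tot > 0 && cnt["C"] / nonref_tot >= psi_dominance
      out$signature[i] <- if (is_psi) "psi" else "?"
    }
  }
  supported <- c(out$position[out$called], external_support)
  for (i in seq_len(n)) {
    if (!out$called[i] && out$delta[i] > neighbor_floor &&
        out$delta[i] <= threshold) {
      d <- abs(supported - out$position[i])
      out$neighbor[i] <- any(d >= 1 & d <= neighbor_window)
    }
  }
  out
}

# Random toy pileup rows (counts) for a given reference base vector.
random_counts <- function(ref_bases, depth = 100, seed = 1) {
  set.seed(seed)
  n <- length(ref_bases)
  out <- data.frame(ref_id = "toy", position = seq_len(n),
                    ref_base = ref_bases, nA = 0L, nC = 0L, nG = 0L, nU = 0L,
                    nDel = rbinom(n, 3, 0.3), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- runif(4); p[match(ref_bases[i], c("A", "C", "G", "U"))] <- 20
    cnt <- as.integer(rmultinom(1, depth, p / sum(p)))
    out[i, c("nA", "nC", "nG", "nU")] <- cnt
  }
  out$depth <- out$nA + out$nC + out$nG + out$nU + out$nDel
  out
}

# Hand-written SAM -> BAM fixture.
write_sam_bam <- function(records, ref_id, ref_len, prefix) {
  sam <- paste0(prefix, ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", ref_id, ref_len),
               records), sam)
  bam <- Rsamtools::asBam(sam, destination = prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

sam_rec <- function(qname, ref, pos, cigar, seq, flag = 0, mapq = 60) {
  paste(qname, flag, ref, pos, mapq, cigar, "*", 0, 0, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

evidence_fixture <- function(name) {
  f <- system.file("extdata", name, package = "deltacall")
  stopifnot(nzchar(f))
  f
}
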