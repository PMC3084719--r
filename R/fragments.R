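# Backbone fragment libraries: candidate-window extraction from monomer
# structures, secondary-structure-aware scoring against the query peptide,
# top-N picking per SS category, and fragment insertion.

#' Secondary-structure label from backbone torsions
#'
#' Torsion-bin rule standing in for a DSSP/STRIDE assignment:
#' H when phi in (-100, -30) and psi in (-80, -5); E when phi in (-180, -60)
#' and psi in (80, 180) or (-180, -170); otherwise C.
#'
#' @param phi,psi Torsions in degrees (vectorized).
#' @return Character vector of labels in `c("H", "E", "C")`.
#' @export
ss_from_torsions <- function(phi, psi) {
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  h <- phi > -100 & phi < -30 & psi > -80 & psi < -5
  e <- phi > -180 & phi < -60 &
    ((psi > 80 & psi < 180) | (psi > -180 & psi < -170))
  ifelse(h, "H", ifelse(e, "E", "C"))
}

#' Secondary-structure prediction matrix
#'
#' @param probs n x 3 matrix of per-residue probabilities with columns
#'   H, E, C; rows must sum to 1 within 1e-6.
#' @return Validated matrix of class `ss_prediction`.
#' @export
ss_prediction <- function(probs) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 3)
  colnames(probs) <- c("H", "E", "C")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("secondary-structure probabilities must sum to 1 per residue")
  }
  structure(probs, class = c("ss_prediction", "matrix"))
}

# helix/strand formers on a Chou-Fasman-like propensity scale
SS_PROPENSITY <- local({
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  h <- c(1.42, 0.98, 0.67, 1.01, 0.70, 1.11, 1.51, 0.57, 1.00, 1.08, 1.21,
         1.16, 1.45, 1.13, 0.57, 0.77, 0.83, 1.08, 0.69, 1.06)
  e <- c(0.83, 0.93, 0.89, 0.54, 1.19, 1.10, 0.37, 0.75, 0.87, 1.60, 1.30,
         0.74, 1.05, 1.38, 0.55, 0.75, 1.19, 1.37, 1.47, 1.70)
  data.frame(aa = aa, h = h, e = e, stringsAsFactors = FALSE)
})

#' Propensity-based fallback secondary-structure predictor
#'
#' A trivial stand-in for an external predictor: per-residue helix/strand
#' propensities smoothed over a 3-residue window and normalized to
#' probabilities (coil receives the constant propensity 1).
#'
#' @param sequence One-letter amino-acid string.
#' @return An [ss_prediction()] matrix.
#' @export
predict_ss_propensity <- function(sequence) {
  seq <- toupper(strsplit(paste(sequence, collapse = ""), "")[[1]])
  idx <- match(seq, SS_PROPENSITY$aa)
  idx[is.na(idx)] <- match("A", SS_PROPENSITY$aa)
  raw <- cbind(H = SS_PROPENSITY$h[idx], E = SS_PROPENSITY$e[idx], C = 1)
  n <- nrow(raw)
  sm <- raw
  for (i in seq_len(n)) {
    w <- max(1, i - 1):min(n, i + 1)
    sm[i, ] <- colMeans(raw[w, , drop = FALSE])
  }
  ss_prediction(sm / rowSums(sm))
}

#' Write / read a secondary-structure prediction (TSV)
#' @param pred An `ss_prediction` matrix.
#' @param path File path.
#' @return Invisibly, the path.
#' @export
write_ss_prediction <- function(pred, path) {
  df <- data.frame(pos = seq_len(nrow(pred)), pH = pred[, "H"],
                   pE = pred[, "E"], pC = pred[, "C"])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ss_prediction
#' @export
read_ss_prediction <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  ss_prediction(cbind(df$pH, df$pE, df$pC))
}

# --- fragment sources -------------------------------------------------------

new_frag_source <- function(id, seq, tor) {
  structure(list(id = id, seq = seq, tor = tor), class = "frag_source")
}

#' Read a fragment source structure from a PDB file
#'
#' Extracts one protein chain, computes backbone torsions, and invalidates
#' torsions around chain breaks (C-N distance > 2 Angstrom) so that windows
#' spanning a break are skipped.
#'
#' @param path PDB file path.
#' @param chain Chain id; default: the first protein chain in the file.
#' @return A `frag_source` object.
#' @export
read_source_structure <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  if (is.null(chain)) chain <- pdb$atom$chain[pdb$atom$type == "ATOM"][1]
  s <- extract_chain_sites(pdb$atom, chain, "fragment source")
  n <- length(s$seq)
  tor <- torsions_from_backbone(s$coords, n)
  tor[n, 2:3] <- NA  # surrogate terminal psi is not fragment material
  # chain breaks: C(i) to N(i+1) distance
  for (i in seq_len(n - 1)) {
    cv <- s$coords[5 * (i - 1) + 3, ]
    nv <- s$coords[5 * i + 1, ]
    if (sqrt(sum((cv - nv)^2)) > 2.0) {
      tor[i, 2:3] <- NA
      tor[i + 1, 1] <- NA
    }
  }
  new_frag_source(basename(path), s$seq, tor)
}

#' Extract candidate fragment windows from source structures
#'
#' Every contiguous window with fully defined torsions yields one candidate
#' with per-position secondary-structure labels assigned by the torsion-bin
#' rule of [ss_from_torsions()].
#'
#' @param sources List of `frag_source` objects (or a single one).
#' @param length Window length (3, 5 or 9).
#' @return List of candidate fragments (class `pep_fragment`).
#' @export
extract_candidate_windows <- function(sources, length) {
  if (inherits(sources, "frag_source")) sources <- list(sources)
  out <- list()
  for (src in sources) {
    n <- nrow(src$tor)
    if (n < length) next
    for (s in seq_len(n - length + 1)) {
      win <- src$tor[s:(s + length - 1), , drop = FALSE]
      if (anyNA(win)) next
      out[[length(out) + 1]] <- structure(list(
        length = length, tor = win,
        ss = ss_from_torsions(win[, 1], win[, 2]),
        seq = src$seq[s:(s + length - 1)],
        source = src$id, start = s, score = NA_real_), class = "pep_fragment")
    }
  }
  if (base::length(out) == 0) warning("no valid windows extracted")
  out
}

# cached BLOSUM62 from Biostrings
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Score a candidate fragment against a query window
#'
#' `score = w_seq * mean(BLOSUM62(query_i, frag_i)) +
#'  w_ss * mean(P(query SS_i = frag label_i))`; higher is better.
#'
#' @param candidate A `pep_fragment`.
#' @param query_window_seq Character vector, same length as the fragment.
#' @param query_window_ss [ss_prediction()] rows for the window.
#' @param w_seq,w_ss Term weights.
#' @return Numeric score.
#' @export
score_fragment <- function(candidate, query_window_seq, query_window_ss,
                           w_seq = 1, w_ss = 2) {
  L <- candidate$length
  if (base::length(query_window_seq) != L || nrow(query_window_ss) != L) {
    stop("query window length does not match fragment length")
  }
  B <- blosum62_matrix()
  qa <- toupper(query_window_seq)
  fa <- toupper(candidate$seq)
  qa[!(qa %in% rownames(B))] <- "X"
  fa[!(fa %in% colnames(B))] <- "X"
  seq_term <- mean(B[cbind(qa, fa)])
  ss_term <- mean(query_window_ss[cbind(seq_len(L),
                                        match(candidate$ss, c("H", "E", "C")))])
  w_seq * seq_term + w_ss * ss_term
}

frag_category <- function(frag) {
  counts <- c(H = sum(frag$ss == "H"), E = sum(frag$ss == "E"),
              C = sum(frag$ss == "C"))
  names(counts)[which.max(counts)]  # ties resolved in H, E, C order
}

# split a per-category quota as evenly as possible over the requested
# lengths, remainders to the shorter lengths
split_quota <- function(per_category, lengths) {
  k <- base::length(lengths)
  q <- rep(per_category %/% k, k)
  extra <- per_category %% k
  if (extra > 0) q[seq_len(extra)] <- q[seq_len(extra)] + 1
  names(q) <- as.character(sort(lengths))
  q
}

#' Pick a fragment library for a query peptide
#'
#' For each secondary-structure category (H, E, C), candidates whose
#' majority label equals the category are ranked by [score_fragment()]
#' (each candidate is scored against its best-matching query window) and
#' the top fragments retained, for a total of `per_category` fragments per
#' category allocated as evenly as possible across the requested lengths.
#' Nonamers are only requested for peptides of nine or more residues.
#'
#' @param query_seq One-letter query peptide string.
#' @param ss_pred [ss_prediction()] for the query.
#' @param pool Candidate list from [extract_candidate_windows()] (lengths
#'   may be mixed).
#' @param per_category Fragments per category (default 500).
#' @param w_seq,w_ss Scoring weights.
#' @return Object of class `fragment_library`.
#' @export
pick_fragments <- function(query_seq, ss_pred, pool, per_category = 500,
                           w_seq = 1, w_ss = 2) {
  if (base::length(pool) == 0) stop("empty candidate pool")
  qseq <- toupper(strsplit(paste(query_seq, collapse = ""), "")[[1]])
  nq <- base::length(qseq)
  pool_lengths <- sort(unique(vapply(pool, function(f) as.integer(f$length), 0L)))
  lengths <- pool_lengths[pool_lengths <= nq & (pool_lengths != 9 | nq >= 9)]
  if (base::length(lengths) == 0) stop("no usable fragment lengths in pool")
  quota <- split_quota(per_category, lengths)
  selected <- list()
  counts <- matrix(0L, base::length(lengths), 3,
                   dimnames = list(as.character(lengths), c("H", "E", "C")))
  for (L in lengths) {
    cands <- Filter(function(f) f$length == L, pool)
    if (base::length(cands) == 0) next
    # score against the best query window
    starts <- seq_len(nq - L + 1)
    scored <- lapply(cands, function(f) {
      sc <- max(vapply(starts, function(s) {
        score_fragment(f, qseq[s:(s + L - 1)],
                       ss_pred[s:(s + L - 1), , drop = FALSE], w_seq, w_ss)
      }, 0))
      f$score <- sc
      f
    })
    cat_of <- vapply(scored, frag_category, "")
    for (cat in c("H", "E", "C")) {
      sub <- scored[cat_of == cat]
      if (base::length(sub) == 0) {
        warning("no ", cat, " candidates of length ", L)
        next
      }
      ord <- order(-vapply(sub, function(f) f$score, 0),
                   vapply(sub, function(f) f$source, ""),
                   vapply(sub, function(f) f$start, 0L))
      take <- min(quota[[as.character(L)]], base::length(sub))
      if (take < quota[[as.character(L)]]) {
        warning("only ", take, " ", cat, " fragments of length ", L,
                " available (wanted ", quota[[as.character(L)]], ")")
      }
      sel <- sub[ord[seq_len(take)]]
      counts[as.character(L), cat] <- take
      selected <- c(selected, sel)
    }
  }
  structure(list(frags = selected, per_category = per_category,
                 lengths = lengths, counts = counts,
                 query = paste(qseq, collapse = "")),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("fragment_library:", base::length(x$frags), "fragments for query",
      x$query, "\n")
  print(x$counts)
  invisible(x)
}

#' Number of fragments per category / in total
#' @param lib A `fragment_library`.
#' @return Named integer vector over categories plus a `total` element.
#' @export
library_counts <- function(lib) {
  per_cat <- colSums(lib$counts)
  c(per_cat, total = sum(per_cat))
}

# stacked torsion matrix of all fragments of one length (for the C++ core)
frag_matrix <- function(lib, length) {
  sel <- Filter(function(f) f$length == length, lib$frags)
  if (base::length(sel) == 0) return(NULL)
  do.call(rbind, lapply(sel, function(f) unname(f$tor)))
}

#' Insert a fragment into the peptide
#'
#' Replaces the peptide torsions covered by the fragment window and
#' rebuilds coordinates; the downstream rigid-body transform is unchanged.
#'
#' @param chain A `pep_chain`.
#' @param fragment A `pep_fragment`.
#' @param start_pos 1-based start position; uniform random when `NULL`.
#' @return The modified chain.
#' @export
insert_fragment <- function(chain, fragment, start_pos = NULL) {
  n <- chain_length(chain)
  L <- fragment$length
  if (L > n) stop("fragment longer than peptide")
  if (is.null(start_pos)) start_pos <- sample.int(n - L + 1, 1)
  if (start_pos < 1 || start_pos + L - 1 > n) stop("start position out of range")
  tor <- chain$tor
  tor[start_pos:(start_pos + L - 1), ] <- fragment$tor
  set_torsions(chain, tor)
}

# --- fragment file format ---------------------------------------------------

#' Write / read a fragment library (tab-separated text)
#'
#' One block per fragment: a header line
#' `frag <length> <source> <start> <score>` followed by one line per
#' position with phi, psi, omega (full precision) and the SS label plus
#' residue type. Round-trips bit-exactly.
#'
#' @param lib A `fragment_library`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fragment_library <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# query %s per_category %d", lib$query,
                     lib$per_category), con)
  for (f in lib$frags) {
    writeLines(sprintf("frag\t%d\t%s\t%d\t%.17g", f$length, f$source,
                       f$start, f$score), con)
    for (i in seq_len(f$length)) {
      writeLines(sprintf("%.17g\t%.17g\t%.17g\t%s\t%s", f$tor[i, 1],
                         f$tor[i, 2], f$tor[i, 3], f$ss[i], f$seq[i]), con)
    }
  }
  invisible(path)
}

#' @rdname write_fragment_library
#' @export
read_fragment_library <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  query <- hdr[3]
  per_category <- as.integer(hdr[5])
  frags <- list()
  i <- 2
  while (i <= base::length(lines)) {
    parts <- strsplit(lines[i], "\t")[[1]]
    stopifnot(parts[1] == "frag")
    L <- as.integer(parts[2])
    rows <- lines[(i + 1):(i + L)]
    cells <- do.call(rbind, strsplit(rows, "\t"))
    tor <- matrix(as.numeric(cells[, 1:3]), L, 3)
    colnames(tor) <- c("phi", "psi", "omega")
    frags[[base::length(frags) + 1]] <- structure(list(
      length = L, tor = tor, ss = cells[, 4], seq = cells[, 5],
      source = parts[3], start = as.integer(parts[4]),
      score = as.numeric(parts[5])), class = "pep_fragment")
    i <- i + L + 1
  }
  lengths <- sort(unique(vapply(frags, function(f) as.integer(f$length), 0L)))
  counts <- matrix(0L, base::length(lengths), 3,
                   dimnames = list(as.character(lengths), c("H", "E", "C")))
  for (f in frags) {
    counts[as.character(f$length), frag_category(f)] <-
      counts[as.character(f$length), frag_category(f)] + 1L
  }
  structure(list(frags = frags, per_category = per_category,
                 lengths = lengths, counts = counts, query = query),
            class = "fragment_library")
}
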