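## Quadripartite plastome structure: LSC - IRb - SSC - IRa, where IRa is the
## reverse complement of IRb (up to a small mismatch fraction). One IR copy
## is removed before cross-species alignment so that mutations inside the
## repeat are not counted twice.
##
## Detection is a seed-and-extend scan of the sequence against its reverse
## complement. A pair of inverted arms [a,b] / [D-b, D-a] lies on a single
## anti-diagonal a+b' = D: position i of the first arm pairs with position
## D-i of the second, and S[i] must equal the complement of S[D-i]. Exact
## k-mer seeds are grouped per anti-diagonal, the longest matching run on
## each diagonal is extended outward while the mismatch fraction stays
## within budget, and the longest qualifying pair wins (ties: smallest
## start coordinate).

.IR_KMER <- 16L

#' Detect the plastome inverted repeat
#'
#' Finds the longest pair of near-exact inverted repeats of at least
#' `min_ir_length` bases. For circular sequences the scan runs on the
#' doubled sequence, and the reported annotation is given on a rotated
#' frame with the canonical LSC-IRb-SSC-IRa order (the applied left
#' rotation is recorded in `offset`).
#'
#' @param seq A single nucleotide string (plastome).
#' @param min_ir_length Minimum acceptable repeat length in bases
#'   (default 1000; true plastome IRs are in the 20-25 kb range).
#' @param max_mismatch_frac Maximum tolerated mismatch fraction between
#'   one arm and the reverse complement of the other (default 0.02).
#' @param circular Treat the sequence as circular.
#' @return A `quadripartite_annotation` object (a list with `ir_length`,
#'   `mismatch_frac`, `offset`, the four canonical intervals `lsc`, `irb`,
#'   `ssc`, `ira` and a `regions` tibble, all 0-based half-open), or `NULL`
#'   when no qualifying repeat exists ("no-IR").
#' @export
detect_inverted_repeat <- function(seq, min_ir_length = 1000,
                                   max_mismatch_frac = 0.02,
                                   circular = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (min_ir_length < 100) abort("min_ir_length must be >= 100")
  s <- toupper(seq)
  L0 <- nchar(s)
  if (L0 < 2 * min_ir_length) {
    abort("sequence shorter than twice min_ir_length")
  }
  ch0 <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(ch0 %in% setdiff(.ALLOWED_SYMBOLS, c("-", "?")))
  if (any(bad)) {
    abort(paste0("non-nucleotide symbol '", ch0[which(bad)[1]],
                 "' at position ", which(bad)[1] - 1L, " (0-based)"))
  }
  S <- if (circular) paste0(s, s) else s
  x <- strsplit(S, "", fixed = TRUE)[[1]]
  cx <- unname(.complement_symbol[x])
  L <- length(x)
  k <- .IR_KMER

  ## exact k-mer seeds between S and revcomp(S)
  n_km <- L - k + 1L
  starts <- seq_len(n_km)
  km_f <- substring(S, starts, starts + k - 1L)
  rc <- paste(rev(cx), collapse = "")
  km_r <- substring(rc, starts, starts + k - 1L)
  pos_f <- split(starts, km_f)
  pos_r <- split(starts, km_r)
  shared <- intersect(names(pos_f), names(pos_r))
  shared <- shared[!str_detect(shared, "N")]
  if (length(shared) == 0) return(NULL)

  best <- NULL
  diag_runs <- new.env(parent = emptyenv())
  for (km in shared) {
    ps <- pos_f[[km]]
    qs <- pos_r[[km]]
    if (length(ps) * length(qs) > 4000) next  # low-complexity guard
    for (p in ps) {
      for (q in qs) {
        m <- L - q - k + 2L          # revcomp arm start in S (1-based)
        if (m <= p) next             # keep first arm first
        D <- p + m + k - 1L          # anti-diagonal index
        key <- as.character(D)
        cur <- diag_runs[[key]]
        diag_runs[[key]] <- if (is.null(cur)) c(p, p + k - 1L) else
          c(min(cur[1], p), max(cur[2], p + k - 1L))
      }
    }
  }
  diags <- ls(diag_runs)
  if (length(diags) == 0) return(NULL)

  for (key in diags) {
    D <- as.integer(key)
    seedspan <- diag_runs[[key]]
    res <- .extend_diagonal(x, cx, D, seedspan, max_mismatch_frac)
    if (is.null(res)) next
    a <- res[1]; b <- res[2]; mm <- res[3]
    len <- b - a + 1L
    if (len < min_ir_length) next
    s2 <- D - b; e2 <- D - a                 # second arm (1-based inclusive)
    if (circular && (e2 - a + 1L) > L0) next # span must fit one genome copy
    if (circular && a > L0) next             # dedupe doubled copies
    cand <- c(a, b, s2, e2, len, mm)
    if (is.null(best) || len > best[5] || (len == best[5] && a < best[1])) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  .build_annotation(best, L0, circular)
}

## Extend the seeded run on anti-diagonal D outward.
## A mismatch is crossed only when the `anchor` positions beyond it all
## match (so scattered mismatches inside a near-identical repeat are
## absorbed, while chance matches in random flanking sequence are not)
## and while the total mismatch fraction stays within budget.
## Returns c(arm1_start, arm1_end, mismatches) 1-based inclusive, or NULL.
.extend_diagonal <- function(x, cx, D, seedspan, max_mm, anchor = 8L) {
  L <- length(x)
  half <- (D - 1L) %/% 2L              # arm1 index must stay < D - index
  lo_lim <- max(1L, D - L)
  hi_lim <- half
  if (hi_lim < lo_lim || seedspan[1] > hi_lim) return(NULL)
  ## match vector over the reachable arm1 indices on this diagonal
  idx <- seq.int(lo_lim, hi_lim)
  match_v <- x[idx] == cx[D - idx]
  nv <- length(match_v)
  ## longest exact run, then anchored outward extension
  r <- rle(match_v)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  bi <- runs[which.max(r$lengths[runs])]
  a_i <- starts[bi]; b_i <- ends[bi]
  mm <- 0L
  repeat {  # leftward
    if (a_i == 1L) break
    if (match_v[a_i - 1L]) { a_i <- a_i - 1L; next }
    lo <- a_i - 1L - anchor
    if (lo < 1L || !all(match_v[lo:(a_i - 2L)])) break
    if (mm + 1L > max_mm * (b_i - a_i + 2L)) break
    mm <- mm + 1L; a_i <- a_i - 1L
  }
  repeat {  # rightward
    if (b_i == nv) break
    if (match_v[b_i + 1L]) { b_i <- b_i + 1L; next }
    hi <- b_i + 1L + anchor
    if (hi > nv || !all(match_v[(b_i + 2L):hi])) break
    if (mm + 1L > max_mm * (b_i - a_i + 2L)) break
    mm <- mm + 1L; b_i <- b_i + 1L
  }
  while (a_i <= b_i && !match_v[a_i]) { a_i <- a_i + 1L; mm <- mm - 1L }
  while (b_i >= a_i && !match_v[b_i]) { b_i <- b_i - 1L; mm <- mm - 1L }
  if (b_i < a_i) return(NULL)
  c(idx[a_i], idx[b_i], mm)
}

## Assemble the annotation object from the winning arm pair.
.build_annotation <- function(best, L0, circular) {
  a <- best[1]; b <- best[2]; s2 <- best[3]; e2 <- best[4]
  len <- best[5]; mm <- best[6]
  offset <- 0L
  if (circular) {
    inner <- s2 - b - 1L
    outer <- L0 - (e2 - a + 1L)  # span a..e2 already includes both arms + inner
    ## rotate so the larger single-copy region (LSC) leads:
    if (outer >= inner) {
      offset <- e2 %% L0                       # start right after arm2
      lsc_len <- outer; irb <- c(lsc_len, lsc_len + len)
      ssc <- c(irb[2], irb[2] + inner)
      ira <- c(ssc[2], ssc[2] + len)
    } else {
      offset <- b %% L0                        # start right after arm1
      lsc_len <- inner; irb <- c(lsc_len, lsc_len + len)
      ssc <- c(irb[2], irb[2] + outer)
      ira <- c(ssc[2], ssc[2] + len)
    }
    lsc <- c(0L, lsc_len)
    regions <- tibble(
      region = c("lsc", "irb", "ssc", "ira"),
      start = c(lsc[1], irb[1], ssc[1], ira[1]),
      end = c(lsc[2], irb[2], ssc[2], ira[2])
    )
  } else {
    lsc <- c(0L, a - 1L)
    irb <- c(a - 1L, b)
    ssc <- c(b, s2 - 1L)
    ira <- c(s2 - 1L, e2)
    regions <- tibble(
      region = c("lsc", "irb", "ssc", "ira"),
      start = c(lsc[1], irb[1], ssc[1], ira[1]),
      end = c(lsc[2], irb[2], ssc[2], ira[2])
    )
    if (e2 < L0) {
      regions <- bind_rows(regions,
                           tibble(region = "lsc_tail",
                                  start = e2, end = L0))
    }
  }
  structure(
    list(ir_length = as.integer(len),
         mismatch_frac = mm / len,
         offset = as.integer(offset),
         circular = circular,
         seq_length = as.integer(L0),
         lsc = as.integer(lsc), irb = as.integer(irb),
         ssc = as.integer(ssc), ira = as.integer(ira),
         regions = regions),
    class = "quadripartite_annotation"
  )
}

#' @export
print.quadripartite_annotation <- function(x, ...) {
  cat("Quadripartite plastome annotation\n")
  cat("  IR length:", x$ir_length, "bp; mismatch fraction:",
      signif(x$mismatch_frac, 3), "\n")
  if (x$offset > 0) cat("  rotated by", x$offset, "bases (circular frame)\n")
  print(x$regions)
  invisible(x)
}

## Rotate a circular sequence left by `offset` bases.
.rotate_seq <- function(s, offset) {
  L <- nchar(s)
  offset <- offset %% L
  if (offset == 0) return(s)
  paste0(str_sub(s, offset + 1, L), str_sub(s, 1, offset))
}

#' Remove the duplicated inverted-repeat copy
#'
#' Returns the sequence in genome order with the IRa copy excised
#' (LSC + IRb + SSC), or with both copies excised when `remove = "both"`.
#' For circular inputs the annotation's rotated frame is used. A `NULL`
#' annotation ("no-IR") returns the sequence unchanged with a warning.
#'
#' @param seq The nucleotide string the annotation was produced from.
#' @param ann A [detect_inverted_repeat()] annotation, or `NULL`.
#' @param remove `"one"` (drop IRa, the default) or `"both"`.
#' @return The reduced nucleotide string.
#' @export
remove_ir_copy <- function(seq, ann, remove = c("one", "both")) {
  remove <- match.arg(remove)
  stopifnot(is.character(seq), length(seq) == 1)
  s <- toupper(seq)
  if (is.null(ann)) {
    warn("no inverted repeat annotated; sequence returned unchanged")
    return(s)
  }
  stopifnot(inherits(ann, "quadripartite_annotation"))
  if (nchar(s) != ann$seq_length) {
    abort("annotation is inconsistent with the sequence (length mismatch)")
  }
  if (any(ann$regions$end > nchar(s)) || any(ann$regions$start < 0)) {
    abort("annotation interval outside sequence bounds")
  }
  s <- .rotate_seq(s, ann$offset)
  drop <- if (remove == "one") "ira" else c("ira", "irb")
  keep <- ann$regions[!(ann$regions$region %in% drop), , drop = FALSE]
  paste(vapply(seq_len(nrow(keep)), function(i) {
    str_sub(s, keep$start[i] + 1, keep$end[i])
  }, character(1)), collapse = "")
}

#' Detect and excise inverted repeats across a FASTA file
#'
#' Convenience wrapper over [detect_inverted_repeat()] and
#' [remove_ir_copy()] for multi-record plastome FASTA files. Records where
#' no IR qualifies pass through unchanged.
#'
#' @param path Input FASTA of unaligned plastomes.
#' @param out_path Optional path for the IR-reduced FASTA.
#' @param ... Passed to [detect_inverted_repeat()].
#' @param remove Passed to [remove_ir_copy()].
#' @return A tibble with one row per record: id, ir_length and the
#'   0-based half-open coordinates of the four regions (NA when no IR).
#' @export
prep_plastomes <- function(path, out_path = NULL, ...,
                           remove = c("one", "both")) {
  remove <- match.arg(remove)
  recs <- seqinr::read.fasta(path, as.string = TRUE,
                             forceDNAtolower = FALSE, whole.header = TRUE)
  if (length(recs) == 0) abort(paste0("malformed or empty FASTA: ", path))
  out_seqs <- list()
  rows <- map_dfr(recs, function(r) {
    id <- attr(r, "name")
    s <- toupper(as.character(r))
    ann <- detect_inverted_repeat(s, ...)
    out_seqs[[id]] <<- suppressWarnings(remove_ir_copy(s, ann, remove))
    if (is.null(ann)) {
      tibble(id = id, ir_length = NA_integer_,
             lsc_start = NA_integer_, lsc_end = NA_integer_,
             irb_start = NA_integer_, irb_end = NA_integer_,
             ssc_start = NA_integer_, ssc_end = NA_integer_,
             ira_start = NA_integer_, ira_end = NA_integer_)
    } else {
      tibble(id = id, ir_length = ann$ir_length,
             lsc_start = ann$lsc[1], lsc_end = ann$lsc[2],
             irb_start = ann$irb[1], irb_end = ann$irb[2],
             ssc_start = ann$ssc[1], ssc_end = ann$ssc[2],
             ira_start = ann$ira[1], ira_end = ann$ira[2])
    }
  })
  if (!is.null(out_path)) {
    seqinr::write.fasta(unname(out_seqs), names = names(out_seqs),
                        file.out = out_path, nbchar = 80)
  }
  rows
}
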