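#' Build a maximal constant-weight-4, distance-4 binary code
#'
#' Constructs the full set of binary words of length `n_bits` with Hamming
#' weight exactly 4 and pairwise Hamming distance at least 4 — equivalently a
#' Steiner quadruple system SQS(`n_bits`): a family of 4-subsets of the bit
#' positions in which every 3-subset of positions occurs in exactly one word.
#' The code size is `choose(n_bits, 3) / 4` (1,240 words at 32 bits). This is
#' the error-robust barcode space used in MERFISH, where weight 4 fixes the
#' number of "on" imaging rounds per RNA species and distance 4 permits
#' single-bit error correction.
#'
#' The code is built by the classical doubling construction: SQS(2n) is the
#' union of two relabelled copies of SQS(n) with cross-blocks pairing
#' same-index one-factors of the complete graph on each copy. The
#' one-factorisation is the canonical round-robin (circle) schedule, so the
#' output is deterministic.
#'
#' @param n_bits Word length; a power of two, at least 4.
#' @return A logical matrix (words x bits); row `i` gives the bits of word `i`.
#' @export
build_max_codebook <- function(n_bits) {
  n_bits <- as.integer(n_bits)
  if (n_bits < 4 || bitwAnd(n_bits, n_bits - 1L) != 0L) {
    abort(sprintf("n_bits must be a power of two >= 4 (got %d)", n_bits))
  }
  blocks <- sqs_blocks(n_bits)
  words <- matrix(FALSE, nrow = nrow(blocks), ncol = n_bits)
  for (i in seq_len(nrow(blocks))) words[i, blocks[i, ]] <- TRUE
  # canonical order: by word value, most significant bit = bit 1
  ord <- do.call(order, as.data.frame(-words))
  words[ord, , drop = FALSE]
}

# Blocks (4-subsets of 1..n) of the Steiner quadruple system SQS(n), n = 2^k.
sqs_blocks <- function(n) {
  if (n == 4L) return(matrix(1:4, nrow = 1))
  h <- n %/% 2L
  base <- sqs_blocks(h)
  copy1 <- base
  copy2 <- base + h
  f <- one_factorization(h)       # list of (h-1) factors, each h/2 x 2
  cross <- vector("list", length(f))
  for (i in seq_along(f)) {
    e1 <- f[[i]]                  # edges on points 1..h
    e2 <- f[[i]] + h              # same factor on the second copy
    combos <- expand.grid(a = seq_len(nrow(e1)), b = seq_len(nrow(e2)))
    cross[[i]] <- cbind(e1[combos$a, 1], e1[combos$a, 2],
                        e2[combos$b, 1], e2[combos$b, 2])
  }
  out <- rbind(copy1, copy2, do.call(rbind, cross))
  t(apply(out, 1, sort))
}

# Round-robin one-factorisation of K_m (m even): m-1 perfect matchings.
one_factorization <- function(m) {
  stopifnot(m %% 2L == 0L)
  lapply(seq_len(m - 1L), function(r) {
    # fix point m; rotate 1..m-1
    edges <- matrix(0L, nrow = m %/% 2L, ncol = 2)
    edges[1, ] <- c(m, r)
    mod1 <- function(v) ((v - 1L) %% (m - 1L)) + 1L
    for (k in seq_len(m %/% 2L - 1L)) {
      edges[k + 1L, ] <- c(mod1(r + k), mod1(r - k))
    }
    t(apply(edges, 1, sort))
  })
}

#' Verify the weight and distance invariants of a codebook
#'
#' Exhaustively checks that every word has the stated Hamming weight and that
#' every pair of words is at least the stated Hamming distance apart.
#' Violations are reported, not raised.
#'
#' @param words A logical/0-1 matrix of words (rows) x bits, or a `codebook`
#'   object from [assign_barcodes()].
#' @param weight,min_distance Expected constant weight and minimum pairwise
#'   distance (defaults 4 and 4).
#' @return A list with `size`, `weight_ok`, `distance_ok` and
#'   `min_pairwise_distance`.
#' @export
verify_codebook <- function(words, weight = 4, min_distance = 4) {
  if (inherits(words, "codebook")) words <- words$words
  w <- matrix(as.numeric(words), nrow = nrow(words))
  if (nrow(w) == 0) abort("empty codebook")
  wt <- rowSums(w)
  weight_ok <- all(wt == weight)
  if (nrow(w) == 1) {
    mind <- Inf
  } else {
    # for constant-weight codes d(a,b) = |a| + |b| - 2 * overlap
    ov <- tcrossprod(w)
    d <- outer(wt, wt, "+") - 2 * ov
    mind <- min(d[upper.tri(d)])
  }
  list(size = nrow(w), weight_ok = weight_ok,
       distance_ok = is.infinite(mind) || mind >= min_distance,
       min_pairwise_distance = mind)
}

#' Assign gene and blank barcodes from a word set
#'
#' Genes receive distinct codewords drawn at random (without replacement)
#' under `seed`; the leftover words become blank barcodes named
#' `Blank-1 ... Blank-k` in canonical word order. Blanks are carried through
#' decoding but map to no gene, providing a false-positive rate readout.
#'
#' @param genes Character vector of gene names.
#' @param words Word matrix from [build_max_codebook()].
#' @param seed Integer seed controlling the random gene-to-word draw.
#' @return A `codebook` object: list with `entries` (tibble of `name`,
#'   `word` bit-string, `is_blank`), `words` (logical matrix, rows aligned
#'   with `entries`), `n_bits`, `weight`, `min_distance`.
#' @export
assign_barcodes <- function(genes, words, seed = 1L) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) abort("gene names must be unique")
  n_words <- nrow(words)
  if (length(genes) > n_words) {
    abort(sprintf("capacity exceeded: %d genes but only %d codewords",
                  length(genes), n_words))
  }
  check_seed(seed)
  gene_rows <- if (length(genes) > 0) sample.int(n_words, length(genes)) else integer(0)
  blank_rows <- setdiff(seq_len(n_words), gene_rows)   # canonical order
  name <- character(n_words)
  name[gene_rows] <- genes
  name[blank_rows] <- paste0("Blank-", seq_along(blank_rows))
  ord <- c(gene_rows, blank_rows)
  w <- words[ord, , drop = FALSE]
  structure(
    list(entries = tibble(name = name[ord],
                          word = apply(w, 1, function(b) paste0(as.integer(b), collapse = "")),
                          is_blank = c(rep(FALSE, length(gene_rows)),
                                       rep(TRUE, length(blank_rows)))),
         words = w, n_bits = ncol(words), weight = 4L, min_distance = 4L),
    class = "codebook"
  )
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> %d-bit HW%d/HD%d: %d genes + %d blanks = %d words\n",
              x$n_bits, x$weight, x$min_distance,
              sum(!x$entries$is_blank), sum(x$entries$is_blank),
              nrow(x$entries)))
  invisible(x)
}

#' Write / read a codebook as CSV
#'
#' Format: a comment header line `# n_bits=..,weight=..,min_distance=..`
#' followed by `name,word` rows; the bit-string is written most significant
#' bit first (bit 1 leftmost).
#'
#' @param codebook A `codebook` object.
#' @param path CSV path.
#' @export
write_codebook <- function(codebook, path) {
  hdr <- sprintf("# n_bits=%d,weight=%d,min_distance=%d",
                 codebook$n_bits, codebook$weight, codebook$min_distance)
  writeLines(c(hdr, "name,word",
               paste(codebook$entries$name, codebook$entries$word, sep = ",")),
             path)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  meta <- as.integer(sub(".*=", "", strsplit(sub("^# ", "", hdr), ",")[[1]]))
  df <- readr::read_csv(paste(lines[-1], collapse = "\n"),
                        col_types = readr::cols(.default = readr::col_character()))
  words <- t(vapply(strsplit(df$word, ""), function(b) as.integer(b) == 1L,
                    logical(meta[1])))
  structure(
    list(entries = tibble(name = df$name, word = df$word,
                          is_blank = startsWith(df$name, "Blank-")),
         words = words, n_bits = meta[1], weight = meta[2], min_distance = meta[3]),
    class = "codebook"
  )
}

#' @method tidy codebook
#' @export
tidy.codebook <- function(x, ...) x$entries

#' @method glance codebook
#' @export
glance.codebook <- function(x, ...) {
  rep <- verify_codebook(x$words, x$weight, x$min_distance)
  tibble(n_bits = x$n_bits, size = rep$size,
         n_genes = sum(!x$entries$is_blank), n_blanks = sum(x$entries$is_blank),
         weight_ok = rep$weight_ok, distance_ok = rep$distance_ok,
         min_pairwise_distance = rep$min_pairwise_distance)
}
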