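# DNA 2-bit encoding and the 2-mer <-> hypercube-node correspondence.
#
# The fixed mapping is T=00, C=01, A=10, G=11 (the .2bit family's common
# dialect), applied letter by letter left to right, so a 2-mer becomes the
# 4-bit label of a hypercube vertex with the first letter on the left.

nucleotide_codes <- c(T = "00", C = "01", A = "10", G = "11")

#' Encode k-mers as hypercube node bits
#'
#' Maps each letter through T=00, C=01, A=10, G=11 and concatenates the
#' 2-bit codes left to right, so a k-mer becomes a 2k-bit node label.
#'
#' @param kmer Character vector of DNA k-mers over \{T, C, A, G\}.
#' @return Character vector of binary node labels, one per k-mer.
#' @export
#' @examples
#' encode_kmer("CA") # "0110"
encode_kmer <- function(kmer) {
  if (!is.character(kmer) || length(kmer) < 1L || anyNA(kmer)) {
    stop("`kmer` must be a character vector of DNA k-mers", call. = FALSE)
  }
  vapply(kmer, function(k) {
    letters <- strsplit(k, "", fixed = TRUE)[[1]]
    bad <- which(!letters %in% names(nucleotide_codes))
    if (length(bad)) {
      stop(
        sprintf("invalid nucleotide '%s' at position %d of \"%s\"",
                letters[bad[1]], bad[1], k),
        call. = FALSE
      )
    }
    paste(nucleotide_codes[letters], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Decode hypercube node bits back to k-mers
#'
#' Exact inverse of [encode_kmer()]: consecutive bit pairs, left to right,
#' become nucleotides.
#'
#' @param bits Character vector of binary node labels of even length.
#' @return Character vector of DNA k-mers.
#' @export
#' @examples
#' decode_node("0110") # "CA"
decode_node <- function(bits) {
  if (!is.character(bits) || length(bits) < 1L || anyNA(bits)) {
    stop("`bits` must be a character vector of binary strings", call. = FALSE)
  }
  letters_by_code <- stats::setNames(names(nucleotide_codes),
                                     nucleotide_codes)
  vapply(bits, function(b) {
    n <- nchar(b)
    if (n %% 2L != 0L || n == 0L) {
      stop(sprintf("node bits \"%s\" must have positive even length", b),
           call. = FALSE)
    }
    check_bits(b, n, "bits")
    pairs <- substring(b, seq(1L, n, by = 2L), seq(2L, n, by = 2L))
    paste(letters_by_code[pairs], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Assemble an 11-character initialization string
#'
#' Concatenates the register components as aux|coin|node|theta, left to
#' right. Because the rightmost character loads qubit 0, theta occupies
#' qubits 0-3, node 4-7, coin 8-9 and aux 10.
#'
#' @param aux 1-character bit (auxiliary qubit).
#' @param coin 2-character binary string.
#' @param node 4-character binary node label (see [encode_kmer()]).
#' @param theta 4-character binary string for the phase-estimation register.
#' @return The 11-character binary initialization string. All arguments are
#'   recycled to a common length; the result has that length.
#' @export
#' @examples
#' build_init_string("0", "10", encode_kmer("CA"), "0010") # "01001100010"
build_init_string <- function(aux, coin, node, theta) {
  n <- max(length(aux), length(coin), length(node), length(theta))
  aux <- rep_len(as.character(aux), n)
  coin <- rep_len(as.character(coin), n)
  node <- rep_len(as.character(node), n)
  theta <- rep_len(as.character(theta), n)
  out <- character(n)
  for (i in seq_len(n)) {
    check_bits(aux[i], 1L, "aux")
    check_bits(coin[i], 2L, "coin")
    check_bits(node[i], 4L, "node")
    check_bits(theta[i], 4L, "theta")
    out[i] <- paste0(aux[i], coin[i], node[i], theta[i])
  }
  out
}

#' Parse initialization strings into register components
#'
#' Exact inverse of [build_init_string()].
#'
#' @param s Character vector of 11-character binary initialization strings.
#' @return A tibble with character columns `aux`, `coin`, `node`, `theta`
#'   (one row per input string).
#' @export
#' @examples
#' parse_init_string("00000110010") # aux 0, coin 00, node 0011, theta 0010
parse_init_string <- function(s) {
  if (!is.character(s) || length(s) < 1L || anyNA(s)) {
    stop("`s` must be a character vector", call. = FALSE)
  }
  for (x in s) check_bits(x, 11L, "s")
  tibble::tibble(
    aux = substr(s, 1L, 1L),
    coin = substr(s, 2L, 3L),
    node = substr(s, 4L, 7L),
    theta = substr(s, 8L, 11L)
  )
}

#' Edges of the n-bit hypercube
#'
#' All unordered pairs of binary vertex labels at Hamming distance 1. An
#' n-bit hypercube has `2^n` vertices and `2^(n-1) * n` edges; for n = 4 the
#' vertices are the 16 encoded 2-mers and every vertex has exactly 4
#' neighbors.
#'
#' @param n_bits Number of bits per vertex label (>= 1).
#' @return A tibble with character columns `from` and `to` (`from` < `to`
#'   lexicographically), one row per edge.
#' @export
#' @examples
#' nrow(hypercube_edges(4)) # 32
hypercube_edges <- function(n_bits) {
  n_bits <- as.integer(n_bits)
  if (length(n_bits) != 1L || is.na(n_bits) || n_bits < 1L) {
    stop("`n_bits` must be a single integer >= 1", call. = FALSE)
  }
  v <- 0:(2^n_bits - 1)
  from <- integer(0)
  to <- integer(0)
  for (b in 0:(n_bits - 1L)) {
    lo <- v[bitwAnd(v, 2^b) == 0L]
    from <- c(from, lo)
    to <- c(to, lo + 2^b)
  }
  tibble::tibble(
    from = int_to_bits(from, n_bits),
    to = int_to_bits(to, n_bits)
  ) |>
    dplyr::arrange(.data$from, .data$to)
}

#' Count k-mers in a FASTA file
#'
#' Slides a window of width `k` across every record of a (multi-record)
#' FASTA file and tallies k-mer occurrences. Lowercase letters are treated
#' as uppercase; windows containing any letter outside \{A, C, G, T\} (e.g.
#' N) are skipped, with a warning when such letters are present.
#'
#' @param path Path to a readable FASTA file.
#' @param k K-mer length (default 2).
#' @return A tibble with columns `kmer`, `node` (the 2-bit-encoded label) and
#'   `count`, one row per k-mer observed at least once, sorted by `kmer`.
#' @export
fasta_kmer_census <- function(path, k = 2L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) {
    stop("`k` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop(sprintf("could not read FASTA file %s: %s",
                   path, conditionMessage(e)), call. = FALSE)
    }
  )
  if (length(seqs) == 0L) {
    stop(sprintf("FASTA file %s contains no records", path), call. = FALSE)
  }
  freq <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  counts <- colSums(freq)
  total_windows <- sum(pmax(Biostrings::width(seqs) - k + 1L, 0L))
  if (sum(counts) < total_windows) {
    warning(
      sprintf("%d window(s) containing non-ACGT letters were skipped",
              total_windows - sum(counts)),
      call. = FALSE
    )
  }
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) {
    return(tibble::tibble(kmer = character(0), node = character(0),
                          count = integer(0)))
  }
  tibble::tibble(
    kmer = names(counts),
    node = encode_kmer(names(counts)),
    count = as.integer(counts)
  ) |>
    dplyr::arrange(.data$kmer)
}
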