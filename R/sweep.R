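# Exhaustive input x mark sweep.
#
# Fast path: the initialization prefix of the circuit only selects a starting
# basis state, so the post-initialization portion of the circuit is a fixed
# unitary per mark. Building that unitary once per mark and reading node
# marginals off its columns replaces 32768 circuit simulations with 16 matrix
# assemblies. The assembly below works on the 10 non-auxiliary qubits (no
# gate touches the auxiliary) ordered theta (low 4 bits) | node | coin
# (high 2 bits), exploiting the register structure: operators acting only on
# theta or only on node+coin are applied blockwise instead of via full
# 1024 x 1024 products, leaving one dense matrix product per oracle +
# phase-estimation iteration.

# --- blockwise operators on the 1024-dim theta(16) x nodecoin(64) space ----

# left-multiply M by I_64 (x) B16 (B acting on the theta register)
theta_op <- function(m, b16) {
  matrix(b16 %*% matrix(m, nrow = 16L), nrow = 1024L)
}

# left-multiply M by A64 (x) I_16 (A acting on the node+coin register)
nodecoin_op <- function(m, a64) {
  arr <- array(m, dim = c(16L, 64L, ncol(m)))
  arr <- aperm(arr, c(2L, 1L, 3L))
  res <- a64 %*% matrix(arr, nrow = 64L)
  arr <- array(res, dim = c(64L, 16L, ncol(m)))
  matrix(aperm(arr, c(2L, 1L, 3L)), nrow = 1024L)
}

# embed a 2x2 unitary on theta qubit k (0..3) into a 16x16 matrix
theta_single <- function(u2, k) {
  lo <- diag(2^k)
  hi <- diag(2^(3L - k))
  kronecker(hi, kronecker(u2, lo))
}

# 16x16 discrete Fourier transform on the theta register (qubit 0 = LSB)
theta_qft_matrix <- function() {
  j <- 0:15
  exp(2i * pi * outer(j, j) / 16) / 4
}

# 64x64 walk operator on node+coin (node = low 4 bits, coin = high 2),
# built by pushing the identity through the walk_step gate sequence.
walk_unitary64 <- function() {
  if (is.null(the_qwalkmer_cache$w64)) {
    loc <- local_walk_layout()
    seq6 <- walk_step(loc)
    the_qwalkmer_cache$w64 <- apply_sequence_matrix(diag(64L) + 0i, seq6, 6L)
  }
  the_qwalkmer_cache$w64
}

h2 <- function() matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)

# Mark-independent pieces of the post-initialization unitary, cached per
# process: the Hadamard prefix on node+coin and the phase-estimation block.
pe_block_matrix <- function() {
  if (is.null(the_qwalkmer_cache$pe)) {
    w <- walk_unitary64()
    wpow <- list(w, w %*% w)
    wpow[[3]] <- wpow[[2]] %*% wpow[[2]]
    wpow[[4]] <- wpow[[3]] %*% wpow[[3]]
    theta_bit <- function(k) bitwAnd(0:1023, 2^k) > 0L
    a <- diag(1024L) + 0i
    for (k in 0:3) {
      a <- theta_op(a, theta_single(h2(), k))
      sel1 <- theta_bit(k)
      a1 <- a
      a1[!sel1, ] <- 0i
      a0 <- a
      a0[sel1, ] <- 0i
      a <- a0 + nodecoin_op(a1, wpow[[k + 1L]])
    }
    f <- theta_qft_matrix()
    refl <- diag(c(-1, rep(1, 15))) + 0i
    b <- theta_op(a, Conj(t(f)))
    b <- theta_op(b, refl)
    b <- theta_op(b, f)
    the_qwalkmer_cache$pe <- Conj(t(a)) %*% b
  }
  the_qwalkmer_cache$pe
}

hadamard_prefix_matrix <- function() {
  if (is.null(the_qwalkmer_cache$hnc)) {
    h64 <- Reduce(kronecker, rep(list(h2()), 6L)) + 0i
    the_qwalkmer_cache$hnc <- nodecoin_op(diag(1024L) + 0i, h64)
  }
  the_qwalkmer_cache$hnc
}

# oracle diagonal over the 1024-dim space: -1 where node register == mark
oracle_diagonal <- function(mark) {
  mv <- strtoi(mark, base = 2L)
  node_of <- bitwAnd(bitwShiftR(0:1023, 4L), 15L)
  ifelse(node_of == mv, -1, 1)
}

# Post-initialization unitary on the 10 non-auxiliary qubits.
mark_unitary10 <- function(mark, iterations = qwalk_iterations()) {
  check_bits(mark, 4L, "mark")
  pe <- pe_block_matrix()
  d <- oracle_diagonal(mark)
  g1 <- pe * rep(d, each = 1024L) # PE %*% diag(d): scale columns
  g <- g1
  if (iterations > 1L) {
    for (r in 2:iterations) g <- g %*% g1
  }
  g %*% hadamard_prefix_matrix()
}

#' Transfer matrix of the post-initialization circuit for one mark
#'
#' The full 2048 x 2048 unitary of everything after the initialization
#' prefix (Hadamards on node and coin, then `iterations` oracle +
#' phase-estimation blocks). Column b is the final state of the register when
#' it starts in basis state b, so [run_search()] probabilities equal the node
#' marginal of the column indexed by the initialization string.
#'
#' @param mark 4-character binary mark.
#' @param iterations Repetitions of the oracle + phase-estimation block.
#' @return A 2048 x 2048 complex matrix.
#' @export
mark_transfer_matrix <- function(mark, iterations = qwalk_iterations()) {
  kronecker(diag(2L), mark_unitary10(mark, iterations))
}

# 16 x 1024 matrix: exact node distribution for every 10-bit start state.
mark_node_probs <- function(mark, iterations = qwalk_iterations()) {
  u <- mark_unitary10(mark, iterations)
  node_of <- bitwAnd(bitwShiftR(0:1023, 4L), 15L)
  p <- rowsum(Mod(u)^2, group = node_of)
  rownames(p) <- node_state_labels()
  p
}

#' Deterministic per-record sampling seed
#'
#' Derives the multinomial sampling seed for one (initialization string,
#' mark) record from the master seed, so every sweep record can be reproduced
#' in isolation by [run_search()].
#'
#' @param master Master integer seed.
#' @param init 11-character binary initialization string.
#' @param mark 4-character binary mark.
#' @return An integer seed in \[0, 2^31).
#' @export
derive_record_seed <- function(master, init, mark) {
  m <- as.numeric(master) %% 2147483647
  h <- (m * 69069 + strtoi(init, base = 2L) * 16 +
          strtoi(mark, base = 2L) + 1) %% 2147483647
  as.integer(h)
}

#' Run the input x mark sweep
#'
#' Executes the walk search for every requested (initialization string, mark)
#' pair at a fixed shot count, via the transfer-matrix fast path. The full
#' sweep covers all 2^11 initialization strings times all 16 marks = 32768
#' records. Records are emitted with initialization strings ascending, marks
#' ascending within each string, and each record's counts are sampled with
#' the seed of [derive_record_seed()], so two sweeps with the same master
#' seed are byte-identical.
#'
#' @param cfg A [search_config()]; `cfg$seed` is the master seed.
#' @param inits Optional character vector restricting the initialization
#'   strings (default: all 2048).
#' @param marks Optional character vector restricting the marks (default:
#'   all 16).
#' @param verbose If `TRUE`, log progress every 1000 records.
#' @return A tibble of run records: `aux`, `coin`, `node`, `theta`, `mark`,
#'   the 16 count columns `"0000"`..`"1111"`, and `shots`.
#' @export
run_sweep <- function(cfg = search_config(), inits = NULL, marks = NULL,
                      verbose = FALSE) {
  if (is.null(inits)) inits <- int_to_bits(0:2047, 11L)
  if (is.null(marks)) marks <- node_state_labels()
  for (x in inits) check_bits(x, 11L, "inits")
  for (x in marks) check_bits(x, 4L, "marks")
  inits <- sort(unique(inits))
  marks <- sort(unique(marks))

  probs <- lapply(marks, mark_node_probs, iterations = cfg$iterations)
  names(probs) <- marks

  n_rec <- length(inits) * length(marks)
  counts <- matrix(0L, nrow = n_rec, ncol = 16L,
                   dimnames = list(NULL, node_state_labels()))
  init_col <- character(n_rec)
  mark_col <- character(n_rec)
  r <- 0L
  for (init in inits) {
    col <- bitwAnd(strtoi(init, base = 2L), 1023L) + 1L
    for (mark in marks) {
      r <- r + 1L
      counts[r, ] <- sample_counts(
        probs[[mark]][, col], cfg$shots,
        derive_record_seed(cfg$seed, init, mark)
      )
      init_col[r] <- init
      mark_col[r] <- mark
      if (verbose && r %% 1000L == 0L) {
        message(sprintf("sweep: %d / %d records", r, n_rec))
      }
    }
  }
  parts <- parse_init_string(init_col)
  dplyr::bind_cols(
    parts,
    tibble::tibble(mark = mark_col),
    tibble::as_tibble(counts),
    tibble::tibble(shots = rep(cfg$shots, n_rec))
  )
}

#' Write sweep records to CSV
#'
#' Column layout mirrors the sweep table: `aux`, `coin`, `node`, `theta`,
#' `mark`, the 16 node-state count columns, `shots`. Binary fields are
#' written as strings (leading zeros preserved); [read_records()] is the
#' exact inverse.
#'
#' @param records A run-record tibble ([run_sweep()] / [run_search()]).
#' @param path Output file path.
#' @return `records`, invisibly.
#' @export
write_records <- function(records, path) {
  cols <- c("aux", "coin", "node", "theta", "mark", node_state_labels(),
            "shots")
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop(sprintf("records are missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  readr::write_csv(records[cols], path, progress = FALSE)
  invisible(records)
}

#' Read sweep records from CSV
#'
#' @param path A CSV file written by [write_records()].
#' @return A run-record tibble.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  ct <- readr::cols(
    aux = readr::col_character(), coin = readr::col_character(),
    node = readr::col_character(), theta = readr::col_character(),
    mark = readr::col_character(),
    shots = readr::col_integer(),
    .default = readr::col_integer()
  )
  rec <- readr::read_csv(path, col_types = ct, progress = FALSE)
  probs <- readr::problems(rec)
  if (nrow(probs) > 0L) {
    stop(sprintf("malformed CSV at line %d: %s",
                 probs$row[1] + 1L, probs$expected[1]), call. = FALSE)
  }
  cols <- c("aux", "coin", "node", "theta", "mark", node_state_labels(),
            "shots")
  missing <- setdiff(cols, names(rec))
  if (length(missing)) {
    stop(sprintf("CSV is missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(rec) > 0L) {
    widths <- c(aux = 1L, coin = 2L, node = 4L, theta = 4L, mark = 4L)
    for (f in names(widths)) {
      bad <- which(!grepl(sprintf("^[01]{%d}$", widths[f]), rec[[f]]))
      if (length(bad)) {
        stop(sprintf("line %d: field `%s` is not a %d-bit binary string",
                     bad[1] + 1L, f, widths[f]), call. = FALSE)
      }
    }
    sums <- rowSums(as.matrix(rec[node_state_labels()]))
    bad <- which(sums != rec$shots)
    if (length(bad)) {
      stop(sprintf("line %d: counts sum to %d but shots = %d",
                   bad[1] + 1L, sums[bad[1]], rec$shots[bad[1]]),
           call. = FALSE)
    }
  }
  rec[cols]
}
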