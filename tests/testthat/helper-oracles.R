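# Independent brute-force oracles used to cross-check the simulator.

# Full 2^n x 2^n matrix of a (multi-)controlled single-qubit gate, built by
# summing Kronecker products over control-bit assignments: for each
# assignment of 0/1 projectors to the control qubits, the target qubit gets
# the 2x2 unitary when all controls are 1 and the identity otherwise.
kron_gate_matrix <- function(n, kind, target, controls = integer(0),
                             angle = NULL) {
  u2 <- switch(kind,
    X = matrix(c(0, 1, 1, 0), 2, 2),
    H = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2),
    Z = diag(c(1, -1)),
    PHASE = diag(c(1, exp(1i * angle)))
  )
  i2 <- diag(2)
  p <- list(diag(c(1, 0)), diag(c(0, 1))) # projectors onto |0>, |1>
  nc <- length(controls)
  total <- matrix(0i, 2^n, 2^n)
  for (assign_id in 0:(2^nc - 1)) {
    bits <- if (nc > 0) bitwAnd(bitwShiftR(assign_id, 0:(nc - 1)), 1L) else
      integer(0)
    term <- matrix(1 + 0i, 1, 1)
    for (q in seq(n - 1, 0)) { # Kronecker from most-significant qubit down
      fac <- if (q == target) {
        if (nc == 0 || all(bits == 1L)) u2 else i2
      } else if (q %in% controls) {
        p[[bits[match(q, controls)] + 1L]]
      } else {
        i2
      }
      term <- kronecker(term, fac)
    }
    total <- total + term
  }
  total
}

# Normalized random complex statevector.
random_state <- function(n, seed) {
  set.seed(seed)
  a <- complex(real = stats::rnorm(2^n), imaginary = stats::rnorm(2^n))
  state_vector(n, a / sqrt(sum(Mod(a)^2)))
}

# Full unitary of a gate sequence (package-internal builder, used where the
# check itself is not about gate application).
seq_unitary <- function(seq, n) {
  qwalkmer:::sequence_unitary(seq, n)
}

# Discrete Fourier transform matrix with qubit 0 as the least-significant
# bit: the reference for the QFT gate construction.
dft_matrix <- function(n) {
  j <- 0:(2^n - 1)
  exp(2i * pi * outer(j, j) / 2^n) / sqrt(2^n)
}

random_bits <- function(n) paste(sample(c("0", "1"), n, TRUE), collapse = "")

# Synthetic complete sweep in which every record has exactly uniform counts.
uniform_sweep <- function(shots = 1024L) {
  inits <- qwalkmer:::int_to_bits(0:2047, 11L)
  marks <- qwalkmer:::node_state_labels()
  init_col <- rep(inits, each = 16L)
  parts <- parse_init_string(init_col)
  cm <- matrix(as.integer(shots / 16L), nrow = length(init_col), ncol = 16L,
               dimnames = list(NULL, marks))
  dplyr::bind_cols(
    parts,
    tibble::tibble(mark = rep(marks, times = length(inits))),
    tibble::as_tibble(cm),
    tibble::tibble(shots = as.integer(shots))
  )
}
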