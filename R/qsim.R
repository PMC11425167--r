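# Exact dense statevector simulator for small registers (<= ~12 qubits).
#
# Conventions used throughout the package:
#   * qubit q is bit q of the basis-state index (qubit 0 = least-significant
#     bit), so a register over n qubits has 2^n amplitudes indexed 0..2^n-1;
#   * bit strings shown to the user read most-significant qubit first, and an
#     n-character string maps its rightmost character onto qubit 0.

#' Construct a statevector
#'
#' A statevector holds the 2^n complex amplitudes of an n-qubit register.
#' Basis index b encodes qubit q as bit q of b (qubit 0 is the
#' least-significant bit). The squared moduli of the amplitudes must sum to 1:
#' they are the probabilities of collapsing into each basis state.
#'
#' @param n_qubits Number of qubits (positive integer).
#' @param amplitudes Complex vector of length `2^n_qubits` with unit 2-norm.
#' @return An object of class `statevector`: a list with elements `n_qubits`
#'   and `amplitudes`.
#' @export
#' @examples
#' state_vector(1, c(1 / sqrt(2), 1i / sqrt(2)))
state_vector <- function(n_qubits, amplitudes) {
  n_qubits <- as.integer(n_qubits)
  if (length(n_qubits) != 1L || is.na(n_qubits) || n_qubits < 1L) {
    stop("`n_qubits` must be a single positive integer", call. = FALSE)
  }
  amplitudes <- as.complex(amplitudes)
  if (length(amplitudes) != 2^n_qubits) {
    stop(
      sprintf(
        "`amplitudes` must have length 2^%d = %d, got %d",
        n_qubits, 2^n_qubits, length(amplitudes)
      ),
      call. = FALSE
    )
  }
  nrm <- sum(Mod(amplitudes)^2)
  if (abs(nrm - 1) > 1e-9) {
    stop(
      sprintf("statevector is not normalized: sum |amp|^2 = %.12f", nrm),
      call. = FALSE
    )
  }
  structure(list(n_qubits = n_qubits, amplitudes = amplitudes),
            class = "statevector")
}

#' @export
print.statevector <- function(x, ...) {
  cat(sprintf("<statevector: %d qubits>\n", x$n_qubits))
  p <- Mod(x$amplitudes)^2
  show <- which(p > 1e-12)
  if (length(show) > 12L) show <- show[order(p[show], decreasing = TRUE)][1:12]
  for (i in sort(show)) {
    cat(sprintf(
      "  |%s>  amp % .6f%+.6fi  p=%.6f\n",
      int_to_bits(i - 1L, x$n_qubits),
      Re(x$amplitudes[i]), Im(x$amplitudes[i]), p[i]
    ))
  }
  invisible(x)
}

#' Prepare a computational basis state from a bit string
#'
#' The rightmost character of `bits` sets qubit 0, so the resulting basis
#' index is simply the integer value of `bits` read as a binary number.
#'
#' @param n Number of qubits.
#' @param bits Binary string of length `n`.
#' @return A [state_vector()] with amplitude 1 on the selected basis state.
#' @export
#' @examples
#' basis_state(2, "10") # amplitude 1 at index 2
basis_state <- function(n, bits) {
  check_bits(bits, n, "bits")
  amps <- complex(2^n)
  amps[strtoi(bits, base = 2L) + 1L] <- 1 + 0i
  state_vector(n, amps)
}

#' Describe one gate of a circuit
#'
#' Supported kinds are the Pauli-X and Z gates, the Hadamard gate, and the
#' single-parameter phase gate. Any gate may carry a set of control qubits:
#' the 2x2 unitary acts on the target only where every control qubit is 1.
#' X with one control is the CNOT; X with two controls is the Toffoli used by
#' the hypercube shift operator.
#'
#' @param kind One of `"X"`, `"H"`, `"Z"`, `"PHASE"`.
#' @param target Target qubit index (0-based).
#' @param controls Integer vector of control qubit indices (possibly empty).
#' @param angle Rotation angle in radians; required for `"PHASE"` only.
#' @return An object of class `gate_step`.
#' @export
#' @examples
#' gate_step("X", target = 0, controls = 1) # CNOT
gate_step <- function(kind, target, controls = integer(0), angle = NULL) {
  kind <- match.arg(kind, c("X", "H", "Z", "PHASE"))
  target <- as.integer(target)
  controls <- as.integer(controls)
  if (length(target) != 1L || is.na(target) || target < 0L) {
    stop("`target` must be a single non-negative qubit index", call. = FALSE)
  }
  if (anyNA(controls) || any(controls < 0L)) {
    stop("`controls` must be non-negative qubit indices", call. = FALSE)
  }
  if (target %in% controls) {
    stop(sprintf("target qubit %d cannot also be a control", target),
         call. = FALSE)
  }
  if (anyDuplicated(controls)) {
    stop("duplicate control qubit indices", call. = FALSE)
  }
  if (kind == "PHASE") {
    if (is.null(angle) || length(angle) != 1L || !is.finite(angle)) {
      stop("PHASE gates require a single finite `angle`", call. = FALSE)
    }
    angle <- as.numeric(angle)
  } else {
    angle <- NULL
  }
  structure(list(kind = kind, target = target, controls = controls,
                 angle = angle),
            class = "gate_step")
}

#' Bundle gate steps into a sequence
#'
#' A gate sequence is an ordered circuit fragment; it is applied left to
#' right by [apply_sequence()].
#'
#' @param ... `gate_step` objects and/or `gate_sequence` objects (spliced).
#' @return An object of class `gate_sequence` (a list of `gate_step`s).
#' @export
gate_sequence <- function(...) {
  parts <- list(...)
  steps <- list()
  for (p in parts) {
    if (inherits(p, "gate_step")) {
      steps[[length(steps) + 1L]] <- p
    } else if (inherits(p, "gate_sequence") || is.list(p)) {
      for (s in p) {
        if (!inherits(s, "gate_step")) {
          stop("gate_sequence() accepts gate_step and gate_sequence objects",
               call. = FALSE)
        }
        steps[[length(steps) + 1L]] <- s
      }
    } else {
      stop("gate_sequence() accepts gate_step and gate_sequence objects",
           call. = FALSE)
    }
  }
  structure(steps, class = "gate_sequence")
}

#' @export
print.gate_sequence <- function(x, ...) {
  cat(sprintf("<gate_sequence: %d steps>\n", length(x)))
  show <- seq_len(min(length(x), 20L))
  for (i in show) {
    s <- x[[i]]
    ctl <- if (length(s$controls)) {
      paste0(" ctrl={", paste(s$controls, collapse = ","), "}")
    } else ""
    ang <- if (!is.null(s$angle)) sprintf(" angle=%.4f", s$angle) else ""
    cat(sprintf("  %3d: %-5s q%d%s%s\n", i, s$kind, s$target, ctl, ang))
  }
  if (length(x) > 20L) cat(sprintf("  ... and %d more\n", length(x) - 20L))
  invisible(x)
}

#' Adjoint (inverse) of a gate sequence
#'
#' Reverses the step order and conjugates each step; X, H, Z are self-adjoint
#' and PHASE(a) becomes PHASE(-a).
#'
#' @param seq A `gate_sequence`.
#' @return The adjoint `gate_sequence`.
#' @export
seq_adjoint <- function(seq) {
  steps <- rev(unclass(seq))
  steps <- lapply(steps, function(s) {
    if (s$kind == "PHASE") s$angle <- -s$angle
    s
  })
  structure(steps, class = "gate_sequence")
}

# 0-based index helpers -------------------------------------------------------

int_to_bits <- function(v, width) {
  vapply(v, function(x) {
    paste(rev(as.integer(intToBits(x))[seq_len(width)]), collapse = "")
  }, character(1))
}

check_bits <- function(bits, n, what) {
  if (!is.character(bits) || length(bits) != 1L || is.na(bits)) {
    stop(sprintf("`%s` must be a single string", what), call. = FALSE)
  }
  if (nchar(bits) != n) {
    stop(sprintf("`%s` must have length %d, got %d", what, n, nchar(bits)),
         call. = FALSE)
  }
  ch <- strsplit(bits, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% c("0", "1"))
  if (length(bad)) {
    stop(
      sprintf("`%s` has non-binary character '%s' at position %d",
              what, ch[bad[1]], bad[1]),
      call. = FALSE
    )
  }
  invisible(bits)
}

# 1-based positions (into the amplitude vector) of basis states with the
# target bit 0 and every control bit 1. The partner position is pos + 2^target.
gate_positions <- function(n, target, controls) {
  if (target >= n || any(controls >= n)) {
    stop(
      sprintf("gate indices must be < %d (target %d, controls {%s})",
              n, target, paste(controls, collapse = ",")),
      call. = FALSE
    )
  }
  idx <- 0:(2^n - 1)
  sel <- bitwAnd(idx, 2^target) == 0L
  for (c in controls) sel <- sel & bitwAnd(idx, 2^c) > 0L
  which(sel)
}

#' Apply one gate to a statevector
#'
#' Applies the standard 2x2 unitary of the step's kind to the target qubit on
#' the subspace where all control qubits are 1, and the identity elsewhere.
#' The 2-norm is preserved.
#'
#' @param state A [state_vector()].
#' @param step A [gate_step()].
#' @return The transformed `statevector`.
#' @export
#' @examples
#' apply_gate(basis_state(1, "0"), gate_step("X", 0)) # |1>
apply_gate <- function(state, step) {
  stopifnot(inherits(state, "statevector"), inherits(step, "gate_step"))
  i0 <- gate_positions(state$n_qubits, step$target, step$controls)
  i1 <- i0 + 2^step$target
  a <- state$amplitudes
  switch(step$kind,
    X = {
      tmp <- a[i0]
      a[i0] <- a[i1]
      a[i1] <- tmp
    },
    H = {
      s <- 1 / sqrt(2)
      a0 <- a[i0]
      a1 <- a[i1]
      a[i0] <- s * (a0 + a1)
      a[i1] <- s * (a0 - a1)
    },
    Z = {
      a[i1] <- -a[i1]
    },
    PHASE = {
      a[i1] <- a[i1] * exp(1i * step$angle)
    }
  )
  state$amplitudes <- a
  state
}

#' Apply a gate sequence to a statevector
#'
#' @param state A [state_vector()].
#' @param seq A [gate_sequence()]; steps are applied left to right.
#' @return The transformed `statevector`.
#' @export
apply_sequence <- function(state, seq) {
  stopifnot(inherits(state, "statevector"))
  for (i in seq_along(seq)) {
    state <- tryCatch(
      apply_gate(state, seq[[i]]),
      error = function(e) {
        stop(sprintf("step %d: %s", i, conditionMessage(e)), call. = FALSE)
      }
    )
  }
  state
}

# Apply a gate step / sequence to every column of a 2^n x m complex matrix
# (each column an amplitude vector). Used to build small unitaries exactly.
apply_gate_matrix <- function(mat, step, n) {
  i0 <- gate_positions(n, step$target, step$controls)
  i1 <- i0 + 2^step$target
  switch(step$kind,
    X = {
      tmp <- mat[i0, , drop = FALSE]
      mat[i0, ] <- mat[i1, , drop = FALSE]
      mat[i1, ] <- tmp
    },
    H = {
      s <- 1 / sqrt(2)
      a0 <- mat[i0, , drop = FALSE]
      a1 <- mat[i1, , drop = FALSE]
      mat[i0, ] <- s * (a0 + a1)
      mat[i1, ] <- s * (a0 - a1)
    },
    Z = {
      mat[i1, ] <- -mat[i1, , drop = FALSE]
    },
    PHASE = {
      mat[i1, ] <- mat[i1, , drop = FALSE] * exp(1i * step$angle)
    }
  )
  mat
}

apply_sequence_matrix <- function(mat, seq, n) {
  for (s in seq) mat <- apply_gate_matrix(mat, s, n)
  mat
}

# Full unitary of a gate sequence on n qubits, built by pushing the identity
# matrix through the circuit (column b = image of basis state b).
sequence_unitary <- function(seq, n) {
  apply_sequence_matrix(diag(2^n) + 0i, seq, n)
}

#' Quantum Fourier transform as a gate sequence
#'
#' Standard textbook construction: a Hadamard plus controlled-PHASE ladder,
#' followed by explicit swap steps (each expanded into three CNOTs) so that
#' the sequence maps the register to its discrete Fourier transform with
#' `qubits[1]` as the least-significant bit. With `inverse = TRUE` the exact
#' adjoint is returned.
#'
#' @param qubits Integer vector of distinct qubit indices, least-significant
#'   first.
#' @param inverse If `TRUE`, return the inverse transform.
#' @return A [gate_sequence()].
#' @export
qft_sequence <- function(qubits, inverse = FALSE) {
  qubits <- as.integer(qubits)
  if (length(qubits) < 1L || anyNA(qubits) || any(qubits < 0L)) {
    stop("`qubits` must be a non-empty vector of qubit indices", call. = FALSE)
  }
  if (anyDuplicated(qubits)) {
    stop("duplicate qubit indices in `qubits`", call. = FALSE)
  }
  n <- length(qubits)
  steps <- list()
  add <- function(s) steps[[length(steps) + 1L]] <<- s
  # rotation ladder, most-significant qubit first
  for (j in seq(n - 1L, 0L)) {
    add(gate_step("H", qubits[j + 1L]))
    if (j > 0L) {
      for (m in seq(j - 1L, 0L)) {
        add(gate_step("PHASE", target = qubits[j + 1L],
                      controls = qubits[m + 1L],
                      angle = pi / 2^(j - m)))
      }
    }
  }
  # bit-reversal swaps, each as three CNOTs
  if (n > 1L) {
    for (i in seq_len(n %/% 2L)) {
      qa <- qubits[i]
      qb <- qubits[n - i + 1L]
      add(gate_step("X", target = qb, controls = qa))
      add(gate_step("X", target = qa, controls = qb))
      add(gate_step("X", target = qb, controls = qa))
    }
  }
  out <- structure(steps, class = "gate_sequence")
  if (inverse) seq_adjoint(out) else out
}

#' Marginal probability distribution of the node register
#'
#' Sums squared amplitude moduli over all basis states sharing each value of
#' the 4-qubit node register, yielding the distribution a measurement of the
#' node qubits would sample from.
#'
#' @param state An 11-qubit [state_vector()].
#' @param layout A [register_layout()].
#' @return Numeric vector of 16 probabilities named `"0000"` to `"1111"`
#'   (node register read most-significant qubit first); sums to 1.
#' @export
node_marginal <- function(state, layout = register_layout()) {
  stopifnot(inherits(state, "statevector"))
  validate_layout(layout)
  if (state$n_qubits <= max(layout$node)) {
    stop("state has too few qubits for this layout", call. = FALSE)
  }
  idx <- 0:(2^state$n_qubits - 1)
  v <- integer(length(idx))
  for (j in seq_along(layout$node)) {
    v <- v + bitwShiftL(as.integer(bitwAnd(idx, 2^layout$node[j]) > 0L), j - 1L)
  }
  p <- as.vector(rowsum(Mod(state$amplitudes)^2, group = v))
  names(p) <- int_to_bits(0:15, 4L)
  p
}

#' Sample measurement counts from a node distribution
#'
#' Draws a seeded multinomial sample of `shots` measurements over the 16 node
#' states. Probabilities off unit sum by less than 1e-9 are renormalized;
#' larger deviations (or negative entries) raise an error.
#'
#' @param probs Numeric vector of 16 probabilities.
#' @param shots Number of measurements (positive integer).
#' @param seed Integer seed; fixing it makes the draw reproducible.
#' @return Integer vector of 16 counts summing to `shots`, named like `probs`.
#' @export
sample_counts <- function(probs, shots, seed) {
  if (length(probs) != 16L) {
    stop("`probs` must have length 16", call. = FALSE)
  }
  if (any(probs < -1e-9)) {
    stop("negative probability in `probs`", call. = FALSE)
  }
  s <- sum(probs)
  if (abs(s - 1) > 1e-9) {
    stop(sprintf("`probs` sums to %.12f, not 1", s), call. = FALSE)
  }
  shots <- as.integer(shots)
  if (length(shots) != 1L || is.na(shots) || shots < 1L) {
    stop("`shots` must be a single positive integer", call. = FALSE)
  }
  probs <- pmax(probs, 0)
  probs <- probs / sum(probs)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  counts <- as.integer(stats::rmultinom(1L, size = shots, prob = probs))
  names(counts) <- if (!is.null(names(probs))) names(probs) else
    int_to_bits(0:15, 4L)
  counts
}
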