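test_that("shift operator moves along hypercube edges, selected by the coin", {
  loc <- qwalkmer:::local_walk_layout() # node on qubits 0-3, coin on 4-5
  shift <- shift_operator(loc)
  for (b in 0:63) {
    st <- basis_state(6, qwalkmer:::int_to_bits(b, 6))
    out <- apply_sequence(st, shift)
    img <- which(Mod(out$amplitudes) > 0.5) - 1L
    expect_length(img, 1L) # permutation of basis states
    node <- b %% 16L
    coin <- b %/% 16L
    # coin value c flips node bit c; coin register is restored
    expect_identical(img, bitwXor(node, bitwShiftL(1L, coin)) + 16L * coin)
    # exactly one node bit changes: a hypercube edge
    expect_identical(sum(bitwAnd(bitwXor(img, b), 15L) %/% 2^(0:3) %% 2), 1)
  }
})

test_that("shift applied twice is the identity", {
  loc <- qwalkmer:::local_walk_layout()
  twice <- gate_sequence(shift_operator(loc), shift_operator(loc))
  u <- seq_unitary(twice, 6)
  expect_lt(max(Mod(u - diag(64))), 1e-9)
})

test_that("the layout-level shift matches the documented node transitions", {
  # coin 00 flips node bit 0; coin 11 flips node bit 3
  shift <- shift_operator(register_layout())
  st <- basis_state(11, "00000000000")
  out <- apply_sequence(st, shift)
  expect_equal(unname(node_marginal(out)[["0001"]]), 1)
  st <- basis_state(11, "01100000000") # coin = 11
  out <- apply_sequence(st, shift)
  expect_equal(unname(node_marginal(out)[["1000"]]), 1)
})

test_that("grover coin is exactly the diffusion 2|s><s| - I on the coin register", {
  u <- seq_unitary(grover_coin(list(coin = 0:1)), 2)
  want <- matrix(1 / 2, 4, 4) - diag(4)
  expect_lt(max(Mod(u - want)), 1e-9)

  # fixes the uniform coin state; applied twice gives the identity
  uniform <- state_vector(2, rep(0.5 + 0i, 4))
  out <- apply_sequence(uniform, grover_coin(list(coin = 0:1)))
  expect_lt(max(Mod(out$amplitudes - uniform$amplitudes)), 1e-9)
  expect_lt(max(Mod(u %*% u - diag(4))), 1e-9)
})

test_that("phase_oracle equals the +/-1 diagonal with -1 exactly at the mark", {
  layout <- register_layout()
  for (mark in c("0000", "0110", "1011")) {
    u <- seq_unitary(phase_oracle(mark, layout), 11)
    node_of <- bitwAnd(bitwShiftR(0:2047, 4L), 15L)
    want_diag <- ifelse(node_of == strtoi(mark, base = 2L), -1, 1)
    expect_lt(max(Mod(u - diag(want_diag))), 1e-9)
  }
  expect_error(phase_oracle("012", layout), "length 4")
})

test_that("walk step equals Shift x (Coin tensor I) as an explicit 64x64 matrix", {
  loc <- qwalkmer:::local_walk_layout()
  got <- seq_unitary(walk_step(loc), 6)
  # independent assembly: permutation matrix for the shift, Kronecker for
  # the coin (coin qubits are the two most-significant local bits)
  coin4 <- matrix(1 / 2, 4, 4) - diag(4)
  cmat <- kronecker(coin4, diag(16)) + 0i
  smat <- matrix(0i, 64, 64)
  for (b in 0:63) {
    img <- bitwXor(b %% 16L, bitwShiftL(1L, b %/% 16L)) + 16L * (b %/% 16L)
    smat[img + 1L, b + 1L] <- 1
  }
  expect_lt(max(Mod(got - smat %*% cmat)), 1e-9)
})

test_that("from the uniform node+coin state the node marginal is invariant under one walk step", {
  layout <- register_layout()
  st <- basis_state(11, strrep("0", 11))
  hs <- lapply(c(layout$node, layout$coin), function(q) gate_step("H", q))
  st <- apply_sequence(st, gate_sequence(hs))
  out <- apply_sequence(st, walk_step(layout))
  expect_lt(max(abs(node_marginal(out) - 1 / 16)), 1e-9)
  expect_lt(abs(sum(Mod(out$amplitudes)^2) - 1), 1e-9)
})

test_that("phase estimation block is unitary and undone by its adjoint", {
  layout <- register_layout()
  pe <- phase_estimation_reflection(layout)
  st <- random_state(11, seed = 11)
  out <- apply_sequence(st, pe)
  expect_lt(abs(sum(Mod(out$amplitudes)^2) - 1), 1e-9)
  back <- apply_sequence(out, seq_adjoint(pe))
  expect_lt(max(Mod(back$amplitudes - st$amplitudes)), 1e-9)
})

test_that("the uniform node+coin state with theta=0 is fixed by the block up to phase", {
  # the uniform state is the walk's zero-phase eigenvector: phase estimation
  # writes theta=0000, the reflection flips it globally, and the unwinding
  # restores the state
  layout <- register_layout()
  st <- basis_state(11, strrep("0", 11))
  hs <- lapply(c(layout$node, layout$coin), function(q) gate_step("H", q))
  st <- apply_sequence(st, gate_sequence(hs))
  out <- apply_sequence(st, phase_estimation_reflection(layout))
  overlap <- sum(Conj(st$amplitudes) * out$amplitudes)
  expect_lt(abs(Mod(overlap) - 1), 1e-9)
})

test_that("build_search_circuit writes the initialization prefix right-to-left", {
  cfg <- search_config(iterations = 1)
  circ <- build_search_circuit("01001100010", "0000", cfg)
  first_h <- Position(function(s) s$kind == "H", circ)
  xs <- circ[seq_len(first_h - 1L)]
  expect_true(all(vapply(xs, function(s) s$kind, "") == "X"))
  # 01001100010 has ones at bit positions 1, 5, 6, 9 (rightmost char = bit 0)
  expect_setequal(vapply(xs, function(s) s$target, integer(1)),
                  c(1L, 5L, 6L, 9L))

  circ0 <- build_search_circuit("00000000000", "0000", cfg)
  expect_identical(circ0[[1]]$kind, "H") # empty X-prefix

  expect_error(build_search_circuit("0100110001", "0000", cfg), "length 11")
  expect_error(build_search_circuit("01001100010", "00100", cfg), "length 4")
})

test_that("the full circuit preserves norm and run_search records are well-formed", {
  cfg <- search_config(shots = 256, seed = 5, iterations = 2)
  circ <- build_search_circuit("01001100010", "1101", cfg)
  out <- apply_sequence(basis_state(11, strrep("0", 11)), circ)
  expect_lt(abs(sum(Mod(out$amplitudes)^2) - 1), 1e-9)

  rec <- run_search("01001100010", "1101", cfg)
  expect_identical(rec$aux, "0")
  expect_identical(rec$coin, "10")
  expect_identical(rec$node, "0110")
  expect_identical(rec$theta, "0010")
  expect_identical(rec$mark, "1101")
  expect_identical(sum(as.matrix(rec[qwalkmer:::node_state_labels()])), 256L)
  # reproducible: the sampling seed is derived from (seed, init, mark)
  rec2 <- run_search("01001100010", "1101", cfg)
  expect_identical(rec, rec2)
})

test_that("all-zeros initialization concentrates hits on the marked state", {
  rec <- run_search("00000000000", "0101", search_config(seed = 3))
  counts <- as.integer(as.matrix(rec[qwalkmer:::node_state_labels()]))
  expect_identical(which.max(counts), strtoi("0101", base = 2L) + 1L)
  expect_gt(counts[strtoi("0101", base = 2L) + 1L], 800)
})

test_that("exact outcome probabilities respect hypercube bit-permutation symmetry", {
  # from the all-zeros initialization, relabeling node bits together with
  # the mark leaves the marked-state probability unchanged
  perms <- list(c(2, 1, 3, 4), c(4, 3, 2, 1), c(2, 3, 4, 1))
  base_mark <- "0011"
  p_base <- exact_node_distribution("00000000000", base_mark)
  for (pm in perms) {
    bits <- strsplit(base_mark, "")[[1]]
    mark2 <- paste(bits[pm], collapse = "")
    p2 <- exact_node_distribution("00000000000", mark2)
    expect_lt(abs(p_base[[base_mark]] - p2[[mark2]]), 1e-9)
  }
})

test_that("the calibrated default iteration count is two", {
  expect_identical(qwalk_iterations(), 2L)
})
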