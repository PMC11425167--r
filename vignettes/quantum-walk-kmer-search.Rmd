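---
title: "Coined quantum walk search on the DNA 2-mer hypercube: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coined quantum walk search on the DNA 2-mer hypercube: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qwalkmer)
```

## The model

The sixteen DNA 2-mers map bijectively onto the vertices of the
4-dimensional hypercube via the 2-bit encoding T=00, C=01, A=10, G=11
(`encode_kmer()` / `decode_node()`); edges connect vertices at Hamming
distance 1, so a single-bit transition is a single "mutation" step in
encoding space. The discrete-time coined quantum walk on this graph lives
on a node register (4 qubits) tensored with a coin register (2 qubits). One
walk step is

$$W = S\,(C \otimes I_{16}),$$

where $C = 2|s\rangle\langle s| - I$ is the Grover diffusion on the coin
($|s\rangle$ the uniform coin state) and the shift $S$ moves the walker
along the edge selected by the coin value $c \in \{0,1,2,3\}$: it flips
node bit $c$ and leaves the coin unchanged. `shift_operator()` transcribes
the standard 12-gate construction (X gates cycling the coin through the
four patterns, each followed by a Toffoli onto one node qubit); the test
suite verifies exhaustively that it is a permutation of the 64 node × coin
basis states that traverses hypercube edges only.

Searching marks one vertex with a phase oracle
$O_m = I - 2\,|m\rangle\langle m|_{\text{node}}$ and amplifies it with a
phase-estimation reflection: with a 4-qubit theta register,

$$
R_{\text{PE}} = A^{\dagger}\,
  \bigl(I - 2\,|0\rangle\langle 0|_{\theta} \otimes I\bigr)\,A,
\qquad
A = \text{(Hadamards on } \theta\text{, then } 2^{k}
  \text{ applications of } W \text{ controlled on } \theta_k\text{, then
  QFT}^{-1}_\theta),
$$

so eigenvectors of $W$ with eigenphase 0 (the walk's stationary component)
pass through unchanged while nonzero-phase components — which the oracle
continually re-creates around the marked vertex — acquire a sign flip.
One search iteration is $R_{\text{PE}} O_m$; `build_search_circuit()`
prepends the initialization X gates and the node/coin Hadamards.

Two sign conventions matter and are easy to get wrong:

* **Coin sign.** The coin is realized as H,H / Z,Z / CZ / H,H, which equals
  $2|s\rangle\langle s| - I$ *exactly*. The alternative X-conjugated CZ
  realization differs by a global phase $-1$ — harmless standalone, fatal
  under control: inside phase estimation a controlled $-W$ shifts every
  eigenphase by $\pi$, the stationary state no longer reads $\theta = 0$,
  and the marked-state probability collapses from 0.886 to 0.03.
* **Reflection sign.** Flipping the $\theta = 0$ component versus flipping
  all $\theta \neq 0$ components differ only by a global phase of the whole
  circuit, which no measurement sees; the package flips $\theta = 0$ (fewer
  gates: X on theta, one 3-control Z, X again).

The QFT dialect, by contrast, does not matter: the reflection is about
$|0\rangle_\theta$, which is invariant under the bit-reversal permutation,
so any DFT-up-to-bit-reversal convention yields the identical circuit
unitary. `qft_sequence()` nevertheless implements the full textbook form
(H + controlled-phase ladder + explicit swap steps) and is tested against
the DFT matrix.

The auxiliary qubit (qubit 10) is touched by no gate at all: the
multi-controlled Z in the reflection is applied directly across the theta
register. Outcome invariance to the auxiliary bit is therefore structural,
but it is still verified numerically (100 random register configurations,
exact marginals equal to 1e-9) because the 11-qubit interface carries the
bit and downstream analysis treats aux = 0/1 strings as distinct inputs.

## Registers, initialization strings and marks

Layout (qubit 0 = least-significant bit of the basis index): theta 0–3,
node 4–7, coin 8–9, aux 10. An 11-character initialization string
concatenates aux|coin|node|theta left to right and loads its rightmost
character into qubit 0, so e.g. "00000110010" sets node = 0011 and theta =
0010. Mark strings are 4 characters, leftmost character on the node
register's most-significant qubit — the same orientation as the node field
of the initialization string, so `encode_kmer("GC")` can be passed directly
as a mark.

## Tunable parameters

* `shots` (default 1024): multinomial sample size per execution. Counts are
  drawn from the exact node marginal; there is no other noise source.
* `iterations` (default `qwalk_iterations()` = 2): repetitions of the
  oracle + reflection block. The reference behavior never states this
  number, so it is fixed by calibration: `calibrate_iterations()` scans
  1..6 and keeps the smallest count whose *exact* marked-state probability
  from the all-zeros initialization lies in [0.83, 0.92] for all 16 marks.
  One iteration gives 0.468, two give 0.88611 (identical across marks, by
  the vertex-transitivity of the hypercube), three overshoot at 0.938.
* `seed`: master seed. Each record's sampling seed is derived as a fixed
  integer hash of (master seed, initialization string, mark)
  (`derive_record_seed()`), so a single sweep record is reproducible in
  isolation by `run_search()` and two equal-seed sweeps are byte-identical.

## The sweep fast path

The initialization prefix only selects a starting basis state, so for a
fixed mark the rest of the circuit is one unitary $U_m$; column $b$ of
$U_m$ is the final state from basis state $b$ (`mark_transfer_matrix()`).
`run_sweep()` assembles $U_m$ blockwise on the 10 non-auxiliary qubits —
theta operators as 16 × 16 blocks, walk powers via the 64 × 64 walk
unitary, the QFT as the DFT matrix — then reads all 1024 node marginals at
once, turning 32768 circuit simulations into 16 matrix assemblies (seconds
rather than hours). Because this path composes explicit matrices while
`run_search()` pushes a statevector through the gate list, their agreement
(tested to 1e-9 on 50 random input–mark pairs) is a meaningful two-route
consistency check, not a tautology.

## Statistics

* **Accuracy** = hits on the marked state / shots.
* **Per-record sigma** (`hit_sigma()`): sample (n−1) standard deviation of
  the 16 counts. A uniform outcome at 1024 shots has expectation 64 per
  state and sigma near 7.8; concentration on few states inflates it.
* **Per-string sigma** (`string_sigma()`): the population standard
  deviation pooled over the string's 16 runs × 16 counts,
  $\sqrt{\tfrac{1}{256}\sum (x - \text{shots}/16)^2}$. Each record's counts
  sum to `shots`, so every record's mean is exactly shots/16 and the pooled
  value equals the RMS of per-record population sigmas. This convention was
  chosen over the mean of per-record sample sigmas by forensics on the
  reference data: recomputing the tabulated Complex-pattern counts gives
  49.259 under this formula against a reported 49.26 (the sample-mean rule
  gives 50.83), and it is what a NumPy `std` call on the 16 × 16 count
  block computes. The two rules differ by ~3%; the choice moves a
  24-string family from σ ≈ 79.2 (where sampling noise pushes ~2 strings
  per run across the Strong boundary at 80) to σ ≈ 76.7, making the
  four-Strong-string census stable across seeds.
* **Categories** (`categorize()`): Random < 14.7 ≤ Emerging < 21 ≤ Weak <
  40 ≤ Complex < 50 ≤ Clear < 80 ≤ Strong, lower bounds inclusive. The
  census of "Random" strings in the discussion of the reference results
  uses a 14.2 cutoff instead of 14.7; `category_census()` therefore exposes
  the scheme as a parameter and the acceptance script counts
  `sigma < 14.2` explicitly.
* **Aux comparison** (`aux_effect()`): absolute per-state hit differences
  between aux = 0/1 paired records, binned in unit-width bins labeled by
  midpoint. The midpoint labeling is a deliberate choice: it reproduces the
  reported non-integer modal value 1.5 (most |differences| between two
  1024-shot draws of near-identical distributions fall in [1, 2)).

## Numerical choices

Dense complex statevector over 2^11 amplitudes; gates act on strided index
pairs; no sparsity or tensor networks at this scale. Norm and identity
tolerances are 1e-9; `sample_counts()` renormalizes probability vectors off
unit sum by less than 1e-9 and errors otherwise. Degenerate inputs
(non-binary strings, length mismatches, duplicate qubit indices,
target-in-controls, incomplete sweeps, unpaired aux records) raise errors
naming the offending position or pairs. All sampling seeds stay below
2^31.

## What the simulation does and does not show

Everything here is *exact* unitary evolution plus multinomial sampling.
That isolates the intrinsic behavior of the circuit: the dependence of
search quality on the initialization string is a property of the algebra,
not of hardware. It deliberately omits what a physical device would add —
gate noise, decoherence, readout error, transpilation to native gate sets —
so measured distributions from real hardware will be flatter than these.
Conclusions about *which* initialization strings are usable transfer only
as upper bounds on performance.

Known limitations: k is fixed at 2 (the node register is 4 qubits; a
different k needs a different hypercube and circuit); the categories are
descriptive thresholds on σ, not inferential statistics; and sampled
quantities near category boundaries (e.g. the Random census at 14.2) can
shift by a few strings between seeds, which the tests' tolerances reflect.

## Reproducibility checks

The test suite cross-checks every gate against a Kronecker-product
brute-force oracle, the QFT against the DFT matrix, the walk step against
an explicitly assembled 64 × 64 matrix, the oracle against the ±1 diagonal,
and the fast path against direct simulation; `scripts/acceptance.R` re-runs
the headline searches, the σ statistics and the full-sweep census from a
single seed. Problem sizes used there: single executions at 1024 shots,
two 16-run σ computations, and one full 2048 × 16 sweep.
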