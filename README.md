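# qwalkmer

Coined quantum walk search on the DNA 2-mer hypercube, simulated exactly —
no quantum SDK required.

## The problem

A DNA k-mer over {T, C, A, G} encodes to 2k bits via the 2-bit mapping
T=00, C=01, A=10, G=11, so the sixteen 2-mers label the vertices of a
4-dimensional hypercube (tesseract) whose edges connect labels at Hamming
distance 1. A *coined quantum walk search* looks for one marked vertex in
this graph: a 2-qubit "coin" register chooses among the four edge
directions, a shift operator moves the walker along the chosen edge, and a
phase-estimation block converts "being the marked vertex" into measurable
amplitude concentration. The full circuit uses 11 qubits:

| register  | qubits | role                                    |
|-----------|--------|-----------------------------------------|
| theta     | 0–3    | phase-estimation readout                |
| node      | 4–7    | hypercube vertex (encoded 2-mer)        |
| coin      | 8–9    | walk direction (Grover coin)            |
| auxiliary | 10     | unused workspace; provably inert here   |

The register is prepared by an 11-character binary *initialization string*
(aux|coin|node|theta, rightmost character → qubit 0). One execution applies
Hadamards to node and coin, then repeats the block

```
O_mark                      phase −1 on the marked node state
A† (I − 2|0⟩⟨0|_theta) A    reflection through the walk's zero-phase space,
                            A = phase estimation of W = S (C ⊗ I)
```

(with C = 2|s⟩⟨s| − I the Grover coin and S the hypercube shift) and finally
measures the node register — here 1024 multinomial "shots" from the exact
node marginal of the statevector. Whether the search *works* depends
dramatically on the initialization string: the package's analysis layer
quantifies that via the standard deviation σ of the 16 hit counts and a
six-way σ category scheme (Random < 14.7 ≤ Emerging < 21 ≤ Weak < 40 ≤
Complex < 50 ≤ Clear < 80 ≤ Strong).

The package provides: an exact dense statevector simulator (`basis_state`,
`apply_gate`, `qft_sequence`, `node_marginal`, `sample_counts`), the circuit
(`shift_operator`, `grover_coin`, `phase_oracle`,
`phase_estimation_reflection`, `build_search_circuit`, `run_search`), the
k-mer layer (`encode_kmer`, `decode_node`, `build_init_string`,
`parse_init_string`, `hypercube_edges`, `fasta_kmer_census`), a
transfer-matrix fast path making the exhaustive 2048 × 16 input × mark sweep
a seconds-scale job (`mark_transfer_matrix`, `run_sweep`), and the analysis
(`accuracy`, `hit_sigma`, `string_sigma`, `categorize`, `category_census`,
`aux_effect`) with ggplot2 views.

## Worked example

```r
library(qwalkmer)

# search for the 2-mer CC (node 0101) from the all-zeros register
rec <- run_search("00000000000", encode_kmer("CC"), search_config(seed = 1))
rec[, c("node", "theta", "mark", "0101", "shots")]
#> # A tibble: 1 × 5
#>   node  theta mark  `0101` shots
#>   <chr> <chr> <chr>  <int> <int>
#> 1 0000  0000  0101     904  1024

accuracy(rec)$accuracy
#> [1] 0.8828125
```

904 of 1024 shots land on the marked vertex: from the all-zeros
initialization the walk finds any marked 2-mer with exact probability
0.8861 (the calibrated two repetitions of the oracle + phase-estimation
block put this in the observed 0.850–0.906 accuracy band for every mark).
Changing a single theta bit flips the behavior to *avoidance*:

```r
rec <- run_search("00000000001", "0000", search_config(seed = 1))
rec[["0000"]]
#> [1] 4        # the marked state is now hit the least of all 16
```

The exhaustive sweep and its census:

```r
sw  <- run_sweep(search_config(seed = 1))   # 32768 records, ~15 s
cen <- category_census(sw)
cen
#> <category_census: 2048 initialization strings>
#>   category n_strings
#> 1 Random        1434
#> 2 Emerging       241
#> 3 Weak           321
#> 4 Complex         24
#> 5 Clear           24
#> 6 Strong           4
#> Strong strings: 00000000000, 00011110001, 10000000000, 10011110001
```

Only four initialization strings (two pairs differing in the inert
auxiliary bit) give the Strong pattern in which the marked k-mer dominates
the measurement; over two thirds of strings collapse to noise. A
command-line front end (`inst/cli/qwalkmer`) exposes `run`, `sweep`,
`kmers`, `analyze` and `aux-effect` subcommands over the same functions.

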