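# Post-processing of sweep records: accuracy, hit-distribution standard
# deviation, sigma categories, the census over initialization strings, and
# the auxiliary-qubit effect comparison.

count_matrix <- function(records) {
  labs <- node_state_labels()
  missing <- setdiff(c(labs, "mark", "shots"), names(records))
  if (length(missing)) {
    stop(sprintf("records are missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  as.matrix(records[labs])
}

init_of <- function(records) {
  paste0(records$aux, records$coin, records$node, records$theta)
}

#' Per-record search accuracy
#'
#' Accuracy is the fraction of shots that hit the marked node state:
#' `counts[mark] / shots`.
#'
#' @param records A run-record tibble ([run_search()] / [run_sweep()]).
#' @return `records` with an `accuracy` column appended.
#' @export
accuracy <- function(records) {
  cm <- count_matrix(records)
  j <- strtoi(records$mark, base = 2L) + 1L
  hits <- cm[cbind(seq_len(nrow(cm)), j)]
  dplyr::mutate(records, accuracy = hits / .data$shots)
}

#' Per-record hit-distribution standard deviation
#'
#' The sample standard deviation (n - 1 denominator) of a record's 16
#' node-state hit counts. Under a uniform (Random) outcome every state is
#' expected near shots/16 hits (64 at 1024 shots) and sigma is small; as
#' hits concentrate on few states, sigma grows.
#'
#' @param records A run-record tibble.
#' @return `records` with a `sigma` column appended.
#' @export
hit_sigma <- function(records) {
  cm <- count_matrix(records)
  dplyr::mutate(records, sigma = apply(cm, 1L, stats::sd))
}

#' Aggregate sigma per initialization string
#'
#' Each initialization string is executed once per mark (16 records); its
#' aggregate sigma is the population standard deviation pooled over all
#' 16 x 16 = 256 counts: `sqrt(mean((count - shots/16)^2))`. Because every
#' record's counts sum to `shots`, each record's mean count is exactly
#' `shots/16`, so this equals the root-mean-square of the per-record
#' population standard deviations and is close to (about 3 percent below)
#' the mean of the per-record sample values of [hit_sigma()].
#'
#' @param records A run-record tibble containing, for every initialization
#'   string present, exactly one record per each of the 16 marks.
#' @return A tibble with one row per initialization string: `init`, `aux`,
#'   `coin`, `node`, `theta`, `sigma`.
#' @export
string_sigma <- function(records) {
  cm <- count_matrix(records)
  records$.sqdev <- rowSums((cm - records$shots / 16)^2)
  records$init <- init_of(records)
  chk <- dplyr::summarise(
    dplyr::group_by(records, .data$init),
    n = dplyr::n(), n_marks = dplyr::n_distinct(.data$mark),
    .groups = "drop"
  )
  bad <- chk[chk$n != 16L | chk$n_marks != 16L, ]
  if (nrow(bad) > 0L) {
    stop(
      sprintf(
        "each initialization string needs exactly one record per mark; offending string(s): %s",
        paste(utils::head(bad$init, 5L), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  dplyr::summarise(
    dplyr::group_by(records, .data$init, .data$aux, .data$coin, .data$node,
                    .data$theta),
    sigma = sqrt(sum(.data$.sqdev) / 256), .groups = "drop"
  ) |>
    dplyr::arrange(.data$init)
}

#' Sigma category scheme
#'
#' Six ordered categories of hit-distribution shape, bounded by sigma
#' thresholds (lower bounds inclusive, upper bounds exclusive): Random
#' (sigma < 14.7, near-uniform), Emerging (14.7-21.0), Weak (21.0-40.0),
#' Complex (40.0-50.0), Clear (50.0-80.0) and Strong (>= 80.0, hits
#' concentrated on the marked state).
#'
#' @param breaks Strictly increasing numeric vector of 5 interior thresholds.
#' @param labels Character vector of 6 category labels.
#' @return An object of class `category_scheme`.
#' @export
category_scheme <- function(breaks = c(14.7, 21, 40, 50, 80),
                            labels = c("Random", "Emerging", "Weak",
                                       "Complex", "Clear", "Strong")) {
  breaks <- as.numeric(breaks)
  if (length(labels) != length(breaks) + 1L) {
    stop("`labels` must have one more element than `breaks`", call. = FALSE)
  }
  if (any(diff(breaks) <= 0) || any(breaks <= 0)) {
    stop("`breaks` must be positive and strictly increasing", call. = FALSE)
  }
  structure(list(breaks = breaks, labels = as.character(labels)),
            class = "category_scheme")
}

#' Categorize sigma values
#'
#' Assigns each sigma to its category interval; lower bounds are inclusive,
#' upper bounds exclusive (a sigma of exactly 14.7 is Emerging, not Random).
#'
#' @param sigma Numeric vector of non-negative standard deviations.
#' @param scheme A [category_scheme()].
#' @return A factor with the scheme's labels as levels.
#' @export
#' @examples
#' categorize(c(5, 28.53, 49.26, 120))
categorize <- function(sigma, scheme = category_scheme()) {
  if (!inherits(scheme, "category_scheme")) {
    stop("`scheme` must be a category_scheme", call. = FALSE)
  }
  if (any(is.na(sigma)) || any(sigma < 0)) {
    stop("`sigma` must be non-negative and non-missing", call. = FALSE)
  }
  cut(sigma, breaks = c(0, scheme$breaks, Inf), labels = scheme$labels,
      right = FALSE, include.lowest = TRUE)
}

#' Census of initialization strings by sigma category
#'
#' From a complete sweep (every initialization string paired with every
#' mark), computes each string's aggregate sigma ([string_sigma()]),
#' categorizes it, and tallies the categories. The aux = 0 and aux = 1
#' variants of a string are counted as distinct strings. Also retains the
#' per-record sigma values underlying the category histograms.
#'
#' @param records A complete run-record sweep ([run_sweep()]).
#' @param scheme A [category_scheme()].
#' @return An object of class `category_census`: a list with
#'   * `strings`: tibble of `init`, `aux`, `coin`, `node`, `theta`, `sigma`,
#'     `category` (one row per initialization string);
#'   * `census`: tibble of `category`, `n_strings`;
#'   * `record_sigma`: tibble of per-record `init`, `mark`, `sigma`,
#'     `category` (the record-level histogram data).
#' @export
category_census <- function(records, scheme = category_scheme()) {
  inits <- init_of(records)
  want <- as.vector(outer(node_state_labels(), int_to_bits(0:2047, 11L),
                          function(m, i) paste(i, m, sep = ":")))
  have <- paste(inits, records$mark, sep = ":")
  missing <- setdiff(want, have)
  if (length(missing)) {
    stop(
      sprintf(
        "incomplete sweep: %d missing (init, mark) pairs, e.g. %s",
        length(missing),
        paste(utils::head(sub(":", " / mark ", missing), 3L),
              collapse = "; ")
      ),
      call. = FALSE
    )
  }
  strings <- string_sigma(records)
  strings$category <- categorize(strings$sigma, scheme)
  census <- dplyr::count(strings, .data$category, name = "n_strings",
                         .drop = FALSE)
  per_rec <- hit_sigma(records)
  record_sigma <- tibble::tibble(
    init = init_of(per_rec),
    mark = per_rec$mark,
    sigma = per_rec$sigma,
    category = categorize(per_rec$sigma, scheme)
  )
  structure(
    list(strings = strings, census = census, record_sigma = record_sigma,
         scheme = scheme),
    class = "category_census"
  )
}

#' @export
print.category_census <- function(x, ...) {
  cat(sprintf("<category_census: %d initialization strings>\n",
              nrow(x$strings)))
  print(x$census)
  strong <- x$strings[x$strings$category == "Strong", ]
  if (nrow(strong) > 0L) {
    cat("Strong strings:", paste(strong$init, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Auxiliary-qubit effect on measured hits
#'
#' For every (coin, node, theta, mark) combination present with both aux = 0
#' and aux = 1, computes the absolute per-state hit differences between the
#' paired records, then summarizes them as a histogram with unit-width bins
#' labeled by midpoint (differences in \[0, 1) fall in the bin at 0.5, etc.),
#' a cumulative distribution, and the modal bin midpoint. Identical paired
#' distributions give differences concentrated at the 0.5 bin; pairs that are
#' independent draws of the same circuit give a right-skewed distribution.
#'
#' @param records A run-record tibble containing aux = 0 / aux = 1 pairs.
#' @return An object of class `aux_effect`: a list with
#'   * `differences`: tibble of `coin`, `node`, `theta`, `mark`, `state`,
#'     `diff` (absolute hit difference);
#'   * `histogram`: tibble of `midpoint`, `n`, `cumulative`;
#'   * `mode`: the modal bin midpoint.
#' @export
aux_effect <- function(records) {
  cm <- count_matrix(records)
  key <- paste(records$coin, records$node, records$theta, records$mark,
               sep = ":")
  a0 <- records$aux == "0"
  a1 <- records$aux == "1"
  k0 <- key[a0]
  k1 <- key[a1]
  if (anyDuplicated(k0) || anyDuplicated(k1)) {
    stop("duplicate records for the same (aux, coin, node, theta, mark)",
         call. = FALSE)
  }
  common <- intersect(k0, k1)
  unpaired <- c(setdiff(k0, k1), setdiff(k1, k0))
  if (length(unpaired)) {
    stop(
      sprintf("unpaired aux records for %d combination(s), e.g. %s",
              length(unpaired), paste(utils::head(unpaired, 3L),
                                      collapse = "; ")),
      call. = FALSE
    )
  }
  if (!length(common)) {
    stop("no aux=0 / aux=1 record pairs found", call. = FALSE)
  }
  m0 <- cm[a0, , drop = FALSE][match(common, k0), , drop = FALSE]
  m1 <- cm[a1, , drop = FALSE][match(common, k1), , drop = FALSE]
  d <- abs(m0 - m1)
  parts <- strsplit(common, ":", fixed = TRUE)
  labs <- node_state_labels()
  differences <- tibble::tibble(
    coin = rep(vapply(parts, `[`, "", 1L), each = 16L),
    node = rep(vapply(parts, `[`, "", 2L), each = 16L),
    theta = rep(vapply(parts, `[`, "", 3L), each = 16L),
    mark = rep(vapply(parts, `[`, "", 4L), each = 16L),
    state = rep(labs, times = length(common)),
    diff = as.integer(t(d))
  )
  bin <- floor(differences$diff)
  midpoints <- seq(0L, max(bin)) + 0.5
  n <- as.integer(table(factor(bin, levels = seq(0L, max(bin)))))
  histogram <- tibble::tibble(
    midpoint = midpoints,
    n = n,
    cumulative = cumsum(n) / sum(n)
  )
  structure(
    list(differences = differences, histogram = histogram,
         mode = midpoints[which.max(n)]),
    class = "aux_effect"
  )
}

#' @export
print.aux_effect <- function(x, ...) {
  cat(sprintf(
    "<aux_effect: %d paired combinations, %d per-state differences>\n",
    nrow(x$differences) / 16L, nrow(x$differences)
  ))
  cat(sprintf("modal |difference| bin midpoint: %.1f\n", x$mode))
  invisible(x)
}
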