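# Transition-balanced trial sequences.
#
# Weight-perception lifting experiments manipulate the one-back weight
# transition (light/heavy x switch/no-switch), so the presentation order must
# contain an exact, equal number of every ordered weight pair.  A sequence of
# 4n + 1 labels with n of each ordered transition is exactly an Eulerian
# circuit of the 2-node multigraph with n parallel edges per ordered pair;
# in- and out-degrees are balanced by construction, so a circuit always
# exists and can be drawn uniformly-at-random with a randomized Hierholzer
# traversal.

WEIGHT_LEVELS <- c("light", "heavy")

#' Generate a transition-balanced pseudo-random trial sequence
#'
#' Builds an ordered sequence of `"light"`/`"heavy"` labels of length
#' `4 * n_per_transition + 1` in which each of the four ordered weight
#' transitions (light-after-light, light-after-heavy, heavy-after-heavy,
#' heavy-after-light) occurs exactly `n_per_transition` times.  The classic
#' design uses `n_per_transition = 20`, i.e. 81 lifts of which the first is
#' discarded, leaving 20 analyzable trials per condition cell.
#'
#' The sequence is a randomized Eulerian circuit of the two-node transition
#' multigraph (Hierholzer's algorithm with shuffled edge order and a uniformly
#' random starting weight), so exact balance holds by construction rather
#' than by rejection sampling.
#'
#' @param n_per_transition Number of occurrences of each ordered weight
#'   transition (positive integer).
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param max_run Optional cap on the longest run of identical labels.  The
#'   classic design imposes none (`Inf`, the default); if finite, sequences
#'   are redrawn (new substream each attempt) until the cap is met.
#' @return An object of class `trial_sequence`: a character vector of labels
#'   with attribute `n_per_transition`.
#' @examples
#' s <- generate_balanced_sequence(20, seed = 1)
#' length(s)            # 81
#' table(head(s, -1), tail(s, -1))  # 20 in every cell
#' @export
generate_balanced_sequence <- function(n_per_transition, seed, max_run = Inf) {
  if (!is_count(n_per_transition)) {
    stop("`n_per_transition` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n_per_transition)
  for (attempt in seq_len(1000L)) {
    labels <- with_seed(substream_seed(seed, attempt - 1L),
                        eulerian_sequence(n))
    if (!is.finite(max_run) || max(rle(labels)$lengths) <= max_run) {
      return(structure(labels,
                       n_per_transition = n,
                       class = "trial_sequence"))
    }
  }
  stop("no sequence satisfying `max_run` found in 1000 attempts",
       call. = FALSE)
}

# Randomized Hierholzer circuit on the 2-node transition multigraph.
# Outgoing edge stacks are pre-shuffled; the stack-based traversal emits the
# circuit's node visitation order (length 4n + 1, first == last node's
# predecessor chain closed).
eulerian_sequence <- function(n) {
  start <- sample(WEIGHT_LEVELS, 1L)
  # outgoing[[v]] is a shuffled stack of edge targets still unused from v
  outgoing <- lapply(WEIGHT_LEVELS, function(v) {
    sample(rep(WEIGHT_LEVELS, each = n))
  })
  names(outgoing) <- WEIGHT_LEVELS
  next_edge <- stats::setNames(c(1L, 1L), WEIGHT_LEVELS)
  stack <- character(4L * n + 1L)
  stack[1L] <- start
  top <- 1L
  circuit <- character(4L * n + 1L)
  filled <- 0L
  while (top > 0L) {
    v <- stack[top]
    i <- next_edge[[v]]
    if (i <= length(outgoing[[v]])) {
      next_edge[[v]] <- i + 1L
      top <- top + 1L
      stack[top] <- outgoing[[v]][i]
    } else {
      filled <- filled + 1L
      circuit[filled] <- v
      top <- top - 1L
    }
  }
  rev(circuit)
}

#' Label trials with their cube and transition condition
#'
#' Converts a label sequence into per-trial condition labels: the first trial
#' of a sequence is `discard` (it follows nothing), and every later trial is
#' `switch` when its weight differs from the preceding trial's weight and
#' `no_switch` otherwise.
#'
#' @param seq A `trial_sequence` or plain character vector of
#'   `"light"`/`"heavy"` labels, length >= 2.
#' @return A tibble with columns `trial` (1-based index), `cube`
#'   (`light`/`heavy`) and `switch` (`switch`/`no_switch`/`discard`).
#' @examples
#' label_transitions(c("light", "heavy", "heavy"))
#' @export
label_transitions <- function(seq) {
  labels <- as.character(seq)
  if (length(labels) < 2L) {
    stop("sequence must contain at least 2 trials", call. = FALSE)
  }
  if (!all(labels %in% WEIGHT_LEVELS)) {
    stop("labels must all be 'light' or 'heavy'", call. = FALSE)
  }
  prev <- c(NA_character_, labels[-length(labels)])
  tibble::tibble(
    trial = seq_along(labels),
    cube = labels,
    switch = dplyr::case_when(
      is.na(prev) ~ "discard",
      prev == labels ~ "no_switch",
      TRUE ~ "switch"
    )
  )
}

#' Check the balance invariants of a trial sequence
#'
#' @param seq Label sequence.
#' @param n_per_transition Expected count per ordered transition; defaults to
#'   the sequence's own attribute.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_sequence <- function(seq,
                              n_per_transition = attr(seq, "n_per_transition")) {
  labels <- as.character(seq)
  n <- n_per_transition
  if (length(labels) != 4L * n + 1L) {
    stop("sequence length ", length(labels), " != 4 * ", n, " + 1",
         call. = FALSE)
  }
  pairs <- table(factor(labels[-length(labels)], WEIGHT_LEVELS),
                 factor(labels[-1L], WEIGHT_LEVELS))
  if (!all(pairs == n)) {
    stop("transition counts are not all ", n, call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a trial sequence as delimited text
#'
#' Two tab-separated columns: `trial_index` (1-based) and `label`.
#'
#' @param seq Label sequence.
#' @param path File path.
#' @return `write_sequence` returns `path` invisibly; `read_sequence` returns
#'   a character label vector.
#' @export
write_sequence <- function(seq, path) {
  utils::write.table(
    data.frame(trial_index = seq_along(seq), label = as.character(seq)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("trial_index", "label") %in% names(df))) {
    stop("sequence file must have columns trial_index, label", call. = FALSE)
  }
  df$label[order(df$trial_index)]
}
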