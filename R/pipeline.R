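#' Design specificity-screened primer pairs
#'
#' Runs the full pipeline: candidate enumeration on both strands, the six
#' single-primer filters, 5' cross-hybridization filtering through the
#' suffix index, general cross-hybridization filtering through pigeonhole
#' seed rounds k = 1..`max_mismatch`, and pair filtering/scoring/ranking.
#' The result is deterministic and identical for every scheduler setting.
#'
#' @param input A FASTA path, a records tibble ([read_fasta()]) or a
#'   `"synthetic_db"` ([generate_db()]).
#' @param config A [pipeline_config()].
#' @return An object of class `"primer_design"`: a list with `pairs` (the
#'   ranked pair tibble), `records`, `config`, `primer_index`, `c4`,
#'   `rounds` and `counts` (valid primer keys after each stage).
#' @export
#' @examples
#' \donttest{
#' db <- generate_db(n_seqs = 6, seq_len = 300, seed = 7)
#' fit <- design_primers(db, pipeline_config(min_tm = 50, max_tm = 65))
#' glance(fit)
#' head(tidy(fit))
#' }
design_primers <- function(input, config = pipeline_config()) {
  records <- if (is.character(input)) {
    read_fasta(input)
  } else if (inherits(input, "synthetic_db")) {
    input$records
  } else {
    as_tibble(input)
  }
  stopifnot(all(c("sid", "seq") %in% names(records)))

  c1 <- enumerate_candidates(records, config$min_len, config$max_len)
  c1p <- aggregate_sidsets(c1)
  pidx <- build_primer_index(c1p, config)
  c2 <- c1[c1$P %in% pidx$P, , drop = FALSE]
  n_single <- nrow(pidx)

  sidx <- build_suffix_index(pidx, config$trim_depth)
  pidx <- filter_5prime(c1p, pidx, sidx, config$trim_depth,
                        skip_invalid = config$probe_skip_invalid)
  n_5p <- sum(pidx$valid)

  ch <- run_crosshyb(c1p, pidx, c2, config$max_mismatch, config)
  pidx <- ch$primer_index

  pairs <- run_pair_step(ch$c4, config, records = records,
                         primer_index = if (config$group_by == "sidset")
                           pidx else NULL)

  counts <- tibble(
    stage = c("candidates", "single_filter", "five_prime",
              paste0("crosshyb_k", seq_len(config$max_mismatch)),
              "pairs"),
    n = c(nrow(c1p), n_single, n_5p,
          n_single_after_rounds(n_5p, ch$rounds),
          nrow(pairs))
  )
  structure(list(pairs = pairs, records = records, config = config,
                 primer_index = pidx, c4 = ch$c4, rounds = ch$rounds,
                 counts = counts),
            class = "primer_design")
}

n_single_after_rounds <- function(n0, rounds) {
  if (nrow(rounds) == 0) return(integer(0))
  n0 - cumsum(rounds$n_invalidated)
}

#' @export
print.primer_design <- function(x, ...) {
  cat("<primer_design>\n")
  cat(sprintf("  %d sequences, %d candidate primer keys\n",
              nrow(x$records), x$counts$n[x$counts$stage == "candidates"]))
  cat(sprintf("  %d valid primers after all filters, %d ranked pairs\n",
              sum(x$primer_index$valid), nrow(x$pairs)))
  invisible(x)
}

#' Broom-style accessors for a primer design
#'
#' `tidy()` returns the ranked pair table, one row per surviving
#' forward/reverse pair; `glance()` returns a one-row summary of the run.
#'
#' @param x A `"primer_design"` object.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy
#' @export
#' @name tidy.primer_design
NULL

#' @rdname tidy.primer_design
#' @export
tidy.primer_design <- function(x, ...) x$pairs

#' @importFrom generics glance
#' @rdname tidy.primer_design
#' @export
glance.primer_design <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$records),
    n_candidates = x$counts$n[x$counts$stage == "candidates"],
    n_single = x$counts$n[x$counts$stage == "single_filter"],
    n_valid = sum(x$primer_index$valid),
    n_pairs = nrow(x$pairs),
    best_penalty = if (nrow(x$pairs)) min(x$pairs$penalty) else NA_real_
  )
}

#' Plot a primer design
#'
#' `type = "attrition"` shows the number of surviving primer keys after
#' each pipeline stage; `type = "penalty"` the penalty distribution of the
#' ranked pairs per target sequence.
#'
#' @param object A `"primer_design"`.
#' @param type Plot type.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.primer_design <- function(object, type = c("attrition", "penalty"),
                                   ...) {
  type <- match.arg(type)
  if (type == "attrition") {
    d <- object$counts
    d$stage <- factor(d$stage, levels = d$stage)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = NULL, y = "surviving keys (log scale)",
                    title = "Filter attrition") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x =
                       ggplot2::element_text(angle = 30, hjust = 1))
  } else {
    d <- object$pairs
    ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$sid),
                                    y = .data$penalty)) +
      ggplot2::geom_boxplot(outlier.size = 0.5) +
      ggplot2::labs(x = "target sequence (sid)", y = "pair penalty",
                    title = "Penalty distribution of ranked pairs") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
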