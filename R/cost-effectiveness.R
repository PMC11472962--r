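#' Outcome measures of an intervention strategy
#'
#' Total addictions averted is the time integral of the difference in the
#' addicted burden (the six classes `IS, PS, IA, PA, CSA, PSA`) between the
#' uncontrolled baseline and the controlled run; total cost incurred is the
#' time integral of the quadratic control effort
#' \eqn{\tfrac12 \sum_i \psi_i w_i^2}. Both use trapezoid quadrature on the
#' shared grid.
#'
#' @param baseline uncontrolled run: an `addiction_trajectory` or an
#'   `addiction_ocp` whose trajectory was obtained with `w = 0`, on the same
#'   initial state, horizon and grid as `result`.
#' @param result an `addiction_ocp` (or list with `trajectory` and `controls`).
#' @param weights a [control_weights()] object.
#' @return List of class `"strategy_outcome"` with `strategy`, `averted`,
#'   `cost`.
#' @export
strategy_outcome <- function(baseline, result, weights = control_weights()) {
  base_tr <- if (inherits(baseline, "addiction_trajectory")) baseline
             else baseline$trajectory
  tr <- result$trajectory
  if (nrow(base_tr) != nrow(tr) ||
      max(abs(base_tr$t - tr$t)) > 1e-9 * max(1, max(abs(tr$t))))
    stop("baseline and result do not share a time grid")
  burden <- function(d) rowSums(d[c("IS", "PS", "IA", "PA", "CSA", "PSA")])
  averted <- pracma::trapz(tr$t, burden(base_tr) - burden(tr))
  W <- as.matrix(result$controls[paste0("w", 1:6)])
  cost <- pracma::trapz(tr$t, as.numeric(0.5 * (W^2 %*% weights$psi)))
  structure(list(strategy = result$strategy %||% "custom",
                 averted = averted, cost = cost),
            class = "strategy_outcome")
}

#' Construct a strategy outcome from known totals
#'
#' @param strategy strategy label.
#' @param averted total addictions averted (person-years).
#' @param cost total intervention cost.
#' @return A `"strategy_outcome"` object.
#' @export
outcome <- function(strategy, averted, cost) {
  structure(list(strategy = strategy, averted = averted, cost = cost),
            class = "strategy_outcome")
}

#' Incremental cost-effectiveness ratio between two outcomes
#'
#' \eqn{(\mathrm{cost}_u - \mathrm{cost}_l)/(\mathrm{averted}_u -
#' \mathrm{averted}_l)}. The first-ranked row of an ICER table uses a zero
#' outcome as `lower`, i.e. its plain cost/averted ratio. May be negative
#' (cheaper and more effective than the comparator).
#'
#' @param lower,upper `"strategy_outcome"` objects (or lists with `averted`
#'   and `cost`); `lower` may be `NULL` for the zero sentinel.
#' @return Scalar ICER.
#' @examples
#' icer_increment(NULL, outcome("E", 1.675e8, 5.262e7))   # ~0.3142
#' @export
icer_increment <- function(lower, upper) {
  if (is.null(lower)) lower <- list(averted = 0, cost = 0)
  d_av <- upper$averted - lower$averted
  if (d_av == 0) stop("identical averted totals: ICER undefined")
  (upper$cost - lower$cost) / d_av
}

#' Build a ranked ICER table
#'
#' Sorts outcomes in ascending order of addictions averted and computes each
#' row's incremental cost-effectiveness ratio against the previous row (the
#' first row against the zero sentinel). Ties in averted are an error: the
#' dominance-elimination procedure has no defined order for them.
#'
#' @param outcomes list of `"strategy_outcome"` objects.
#' @return Object of class `"icer_table"`: data frame with columns `strategy`,
#'   `averted`, `cost`, `icer`.
#' @examples
#' tab <- build_icer_table(list(outcome("E", 1.675e8, 5.262e7),
#'                              outcome("C", 2.618e8, 5.559e7),
#'                              outcome("D", 4.897e8, 3.882e7)))
#' tab
#' @export
build_icer_table <- function(outcomes) {
  if (inherits(outcomes, "strategy_outcome")) outcomes <- list(outcomes)
  if (!length(outcomes)) stop("need at least one outcome")
  df <- data.frame(
    strategy = vapply(outcomes, function(o) o$strategy, character(1)),
    averted = vapply(outcomes, function(o) o$averted, numeric(1)),
    cost = vapply(outcomes, function(o) o$cost, numeric(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$averted)) {
    dup <- df$strategy[df$averted %in% df$averted[duplicated(df$averted)]]
    stop("tied averted totals between strategies ",
         paste(dup, collapse = ", "), ": ranking undefined")
  }
  df <- df[order(df$averted), , drop = FALSE]
  rownames(df) <- NULL
  df$icer <- NA_real_
  prev <- NULL
  for (i in seq_len(nrow(df))) {
    df$icer[i] <- icer_increment(prev, df[i, ])
    prev <- df[i, ]
  }
  class(df) <- c("icer_table", "data.frame")
  df
}

#' @export
print.icer_table <- function(x, ...) {
  cat("ICER table (ascending addictions averted):\n")
  y <- as.data.frame(x)
  y$averted <- signif(y$averted, 5)
  y$cost <- signif(y$cost, 5)
  y$icer <- signif(y$icer, 5)
  print(y, row.names = FALSE)
  hist <- attr(x, "elimination")
  if (!is.null(hist) && nrow(hist)) {
    cat("elimination rounds:\n")
    print(as.data.frame(hist), row.names = FALSE)
    cat("most cost-effective strategy:", attr(x, "winner"), "\n")
  }
  invisible(x)
}

#' Iterative dominance elimination
#'
#' Repeatedly removes the strategy with the largest ICER (the dominated one:
#' highest cost per additional addiction averted) and rebuilds the incremental
#' ratios, until a single strategy — the most cost-effective — remains.
#' Negative ICERs (cheaper and more effective) are never the maximum of a
#' round, so such strategies always survive it. Equal maximal ICERs are an
#' error rather than silently broken.
#'
#' @param table an `"icer_table"` (or list of outcomes, which is ranked
#'   first).
#' @return The final one-row `"icer_table"`, with attributes `elimination`
#'   (data frame: round, removed strategy, its ICER) and `winner`, plus
#'   `rounds` — the list of intermediate tables.
#' @examples
#' tab <- build_icer_table(list(outcome("E", 1.675e8, 5.262e7),
#'                              outcome("C", 2.618e8, 5.559e7),
#'                              outcome("D", 4.897e8, 3.882e7)))
#' attr(eliminate_dominated(tab), "winner")   # "D"
#' @export
eliminate_dominated <- function(table) {
  if (!inherits(table, "icer_table")) table <- build_icer_table(table)
  rounds <- list(table)
  hist <- data.frame(round = integer(), removed = character(),
                     icer = numeric(), stringsAsFactors = FALSE)
  round <- 0L
  while (nrow(table) > 1L) {
    round <- round + 1L
    mx <- which(table$icer == max(table$icer))
    if (length(mx) > 1L)
      stop("equal maximal ICERs between strategies ",
           paste(table$strategy[mx], collapse = ", "),
           ": elimination order undefined")
    hist <- rbind(hist, data.frame(round = round,
                                   removed = table$strategy[mx],
                                   icer = table$icer[mx],
                                   stringsAsFactors = FALSE))
    keep <- table[-mx, c("strategy", "averted", "cost"), drop = FALSE]
    table <- build_icer_table(lapply(seq_len(nrow(keep)), function(i)
      outcome(keep$strategy[i], keep$averted[i], keep$cost[i])))
    rounds <- c(rounds, list(table))
  }
  attr(table, "elimination") <- hist
  attr(table, "winner") <- table$strategy[1L]
  attr(table, "rounds") <- rounds
  table
}

#' Overall cost-effectiveness comparison
#'
#' Ranks the per-case winning strategies against each other and runs the
#' dominance elimination; the survivor is the headline recommendation.
#'
#' @param case_winners list of `"strategy_outcome"` objects (one per case).
#' @return An `"icer_table"` as returned by [eliminate_dominated()] (the
#'   single winner, with elimination history), or the input table unchanged
#'   when only one winner is supplied.
#' @export
overall_comparison <- function(case_winners) {
  tab <- build_icer_table(case_winners)
  if (nrow(tab) == 1L) {
    attr(tab, "winner") <- tab$strategy[1L]
    attr(tab, "elimination") <- data.frame(round = integer(),
                                           removed = character(),
                                           icer = numeric())
    return(tab)
  }
  eliminate_dominated(tab)
}

#' Reference strategy outcomes for the worked examples
#'
#' Bundled averted/cost totals for the nine intervention strategies, grouped
#' the way the cost-effectiveness worked examples analyse them: `case1`
#' compares the two three-control strategies (A, B), `case2` the four-control
#' strategies (E, C, D), `case3` the five-control strategies (H, G, F),
#' `case4` the all-controls strategy (I), and `overall` the four per-case
#' winners (A, F, I, D). These reference totals let the ICER machinery be
#' exercised and checked without re-running the optimal-control simulations
#' that produced them (whose initial conditions and horizon are not part of
#' the reference material).
#'
#' @param case one of `"case1"`, `"case2"`, `"case3"`, `"case4"`, `"overall"`.
#' @return List of `"strategy_outcome"` objects.
#' @examples
#' attr(eliminate_dominated(build_icer_table(reference_outcomes("case2"))),
#'      "winner")    # "D"
#' @export
reference_outcomes <- function(case = c("case1", "case2", "case3", "case4",
                                        "overall")) {
  case <- match.arg(case)
  switch(case,
    case1 = list(outcome("B", 4.3655e6, 2.1716e5),
                 outcome("A", 4.6790e6, 2.6261e5)),
    case2 = list(outcome("E", 1.675e8, 5.262e7),
                 outcome("C", 2.618e8, 5.559e7),
                 outcome("D", 4.897e8, 3.882e7)),
    case3 = list(outcome("H", 9.772e6, 1.1559e6),
                 outcome("G", 1.211e7, 1.6415e6),
                 outcome("F", 1.331e7, 9.1930e5)),
    # strategy I's cost: of the two published variants (1.9857e7 / 1.9857e6)
    # only the latter is consistent with the overall table's own ratios
    case4 = list(outcome("I", 1.4354e7, 1.9857e6)),
    overall = list(outcome("A", 4.6790e6, 2.6261e5),
                   outcome("F", 1.331e7, 9.1930e5),
                   outcome("I", 1.4354e7, 1.9857e6),
                   outcome("D", 4.897e8, 3.882e7)))
}

#' Read / write strategy outcomes as CSV
#'
#' Plain `strategy,averted,cost` tables.
#'
#' @param path file path.
#' @return `read_outcomes`: list of `"strategy_outcome"` objects.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strategy", "averted", "cost")
  if (!all(need %in% names(df)))
    stop("outcomes CSV must have columns strategy, averted, cost")
  lapply(seq_len(nrow(df)), function(i)
    outcome(df$strategy[i], df$averted[i], df$cost[i]))
}

#' @rdname read_outcomes
#' @param outcomes list of `"strategy_outcome"` objects.
#' @export
write_outcomes <- function(outcomes, path) {
  df <- data.frame(strategy = vapply(outcomes, `[[`, "", "strategy"),
                   averted = vapply(outcomes, `[[`, 0, "averted"),
                   cost = vapply(outcomes, `[[`, 0, "cost"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
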