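#' Default speller alphabet
#'
#' 65 symbols: the 26 letters, 10 digits, space, common punctuation and a few
#' control tokens -- the smallest round symbol set that fills four levels of a
#' four-way division layout (4^4 = 256 >= 65 with every symbol at depth 4 on
#' a balanced tree of depth ceiling(log4 65) = 4) and seven levels of a
#' two-way layout (depth 7).
#'
#' @return Character vector of 65 symbols.
#' @export
default_alphabet <- function() {
  out <- c(
    letters, as.character(0:9), " ",
    ".", ",", "?", "!", "'", "\"", ":", ";", "-", "(", ")", "/", "@", "&",
    "<enter>", "<space>", "<del>", "<clear>", "<up>", "<down>", "<left>",
    "<right>", "<home>", "<end>", "<esc>", "<tab>", "<shift>", "<menu>"
  )
  stopifnot(length(out) == 65)
  out
}

#' Speller command-to-quadrant assignment
#'
#' The four recognized patterns map to screen quadrants: right eye movement
#' selects the lower-right area, left eye movement the lower-left, a right
#' blink the upper-right, a left blink the upper-left. In a k = 2 layout only
#' the first two commands of the chosen modality are used.
#'
#' @param k Branching factor (2 or 4).
#' @return Character vector of commands in branch order (branch 1, 2, ...).
#' @export
speller_commands <- function(k = 4) {
  cmds <- c("left_blink", "right_blink", "left", "right") # UL, UR, LL, LR
  if (k == 4) cmds else cmds[3:4]
}

#' Build a division-selection tree
#'
#' Balanced k-ary tree of depth `ceiling(log_k(length(alphabet)))` with the
#' symbols at the leaves in alphabet order; each command narrows the
#' candidate set by a factor of k until one symbol remains.
#'
#' @param alphabet Ordered, non-empty symbol vector.
#' @param k Branching factor, 2 or 4.
#' @return A tibble of class `selection_tree` with columns `symbol`, `depth`,
#'   `code` (branch digits, 0-based), and `commands` (list column of command
#'   sequences); attributes `alphabet` and `k`.
#' @examples
#' tree <- build_tree(default_alphabet(), k = 4)
#' unique(tree$depth)  # 4
#' @export
build_tree <- function(alphabet = default_alphabet(), k = 4) {
  if (length(alphabet) == 0) {
    stop_invalid_argument("`alphabet` must be non-empty.")
  }
  if (anyDuplicated(alphabet)) {
    stop_invalid_argument("`alphabet` symbols must be unique.")
  }
  if (!k %in% c(2, 4)) stop_invalid_argument("`k` must be 2 or 4.")
  n <- length(alphabet)
  depth <- max(1L, as.integer(ceiling(log(n) / log(k) - 1e-9)))
  cmds <- speller_commands(k)
  codes <- vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(depth)
    for (d in depth:1) {
      digits[d] <- i %% k
      i <- i %/% k
    }
    paste(digits, collapse = "")
  }, character(1))
  out <- tibble(
    symbol = alphabet,
    depth = depth,
    code = codes,
    commands = lapply(strsplit(codes, ""), function(d) cmds[as.integer(d) + 1L])
  )
  attr(out, "alphabet") <- alphabet
  attr(out, "k") <- k
  class(out) <- c("selection_tree", class(out))
  out
}

#' Speller timing and error-model configuration
#'
#' @param control_interval Recognizer polling interval in seconds.
#' @param per_operation_time Mean wall time per issued command, seconds
#'   (an input to the arithmetic, not derived from signal simulation, so
#'   throughput results are reproducible independently of recognizer
#'   accuracy). The default is the observed four-division pace, 50.0 s / 32
#'   operations.
#' @param miss_prob Probability a command is recognized as a wrong pattern
#'   (selects a wrong branch).
#' @param reject_prob Probability a command is not recognized at all (the
#'   operation is repeated).
#' @param scan_period Auto-scan dwell per symbol, seconds (scanner mode).
#' @return A list of class `speller_config`.
#' @export
speller_config <- function(control_interval = 0.1,
                           per_operation_time = 1.5625,
                           miss_prob = 0,
                           reject_prob = 0,
                           scan_period = 1) {
  assert_scalar_number(control_interval, "control_interval", 0, strict = TRUE)
  assert_scalar_number(per_operation_time, "per_operation_time", 0, strict = TRUE)
  for (nm in c("miss_prob", "reject_prob")) {
    p <- get(nm)
    assert_scalar_number(p, nm, 0)
    if (p > 1) stop_invalid_argument(sprintf("`%s` must be in [0, 1].", nm))
  }
  assert_scalar_number(scan_period, "scan_period", 0, strict = TRUE)
  structure(
    list(control_interval = control_interval,
         per_operation_time = per_operation_time,
         miss_prob = miss_prob, reject_prob = reject_prob,
         scan_period = scan_period),
    class = "speller_config"
  )
}

new_speller_result <- function(total_time, operations, misses, transcript,
                               log, timeout = FALSE) {
  structure(
    list(total_time = total_time, operations = operations, misses = misses,
         miss_rate = if (operations > 0) 100 * misses / operations else 0,
         transcript = transcript, log = log, timeout = timeout),
    class = "speller_result"
  )
}

#' @export
print.speller_result <- function(x, ...) {
  cat(sprintf(
    "<speller_result> \"%s\": %d operations, %.1f s, miss rate %.2f%%%s\n",
    x$transcript, x$operations, x$total_time, x$miss_rate,
    if (x$timeout) " [timeout]" else ""
  ))
  invisible(x)
}

#' @rdname simulate_spelling
#' @param x A `speller_result`.
#' @param ... Unused.
#' @export
tidy.speller_result <- function(x, ...) x$log

#' Simulate division-selection character input
#'
#' Walks the selection tree once per character of `text`, issuing one command
#' per tree level at `per_operation_time` seconds each. Under the error
#' model, a rejected command costs one operation and repeats the step; a
#' missed command selects a wrong branch, after which the user restarts the
#' descent for the current character (the partial path is wasted).
#'
#' @param text Character string; every symbol must be in the tree's alphabet.
#' @param tree A [build_tree()] selection tree.
#' @param cfg A [speller_config()].
#' @param seed Integer seed; results are deterministic given the seed.
#' @param max_ops_per_char Safety cap before a character times out.
#' @return A `speller_result`: `total_time` (s), `operations`, `misses`,
#'   `miss_rate` (% of operations), `transcript`, and a per-operation `log`
#'   tibble (also available via [tidy()]).
#' @examples
#' tree <- build_tree(default_alphabet(), k = 4)
#' simulate_spelling("miyazaki", tree, speller_config(), seed = 1)
#' @export
simulate_spelling <- function(text, tree, cfg = speller_config(), seed = 1L,
                              max_ops_per_char = 1000L) {
  stopifnot(inherits(tree, "selection_tree"), inherits(cfg, "speller_config"))
  symbols <- if (nchar(text) > 0) tokenize_text(text, attr(tree, "alphabet"))
             else character(0)
  log_rows <- list()
  ops <- 0L; misses <- 0L; timeout <- FALSE
  withr::with_seed(as.integer(seed), {
    for (si in seq_along(symbols)) {
      target <- symbols[si]
      path <- tree$commands[[match(target, tree$symbol)]]
      step <- 1L
      char_ops <- 0L
      while (step <= length(path)) {
        if (char_ops >= max_ops_per_char) { timeout <- TRUE; break }
        u <- runif(1)
        ops <- ops + 1L
        char_ops <- char_ops + 1L
        cmd <- path[step]
        if (u < cfg$reject_prob) {
          result <- "reject"                     # no reaction; retry step
        } else if (u < cfg$reject_prob + cfg$miss_prob) {
          result <- "miss"                       # wrong branch; restart char
          misses <- misses + 1L
          step <- 1L
        } else {
          result <- "ok"
          step <- step + 1L
        }
        log_rows[[length(log_rows) + 1L]] <-
          tibble(symbol = target, command = cmd, result = result)
      }
      if (timeout) break
    }
  })
  log <- if (length(log_rows)) bind_rows(log_rows) else
    tibble(symbol = character(0), command = character(0), result = character(0))
  new_speller_result(
    total_time = ops * cfg$per_operation_time,
    operations = ops, misses = misses,
    transcript = paste(symbols[seq_len(if (timeout) 0 else length(symbols))],
                       collapse = ""),
    log = log, timeout = timeout
  )
}

# Split text into alphabet symbols (single characters; multi-character
# control tokens are matched when delimited by '<...>').
tokenize_text <- function(text, alphabet) {
  chars <- regmatches(text, gregexpr("<[^>]+>|.", text))[[1]]
  bad <- setdiff(chars, alphabet)
  if (length(bad) > 0) {
    stop_invalid_argument(paste0(
      "Symbol(s) not in alphabet: ", paste(unique(bad), collapse = ", ")
    ))
  }
  chars
}

#' Simulate single-click auto-scan character input
#'
#' The software highlights the alphabet symbols one after another for
#' `scan_period` seconds each; the user issues a single recognized pattern
#' (a click) when the target symbol is highlighted. A failed click
#' (probability `miss_prob`) lets the scan run a full further cycle before
#' the next attempt. Scanning restarts from the first symbol for each
#' character.
#'
#' @param text Character string to input.
#' @param alphabet Symbol vector scanned in order.
#' @param scan_period Dwell time per symbol, seconds.
#' @param miss_prob Probability a click is not recognized.
#' @param seed Integer seed.
#' @param max_cycles Cap on scan cycles per character; exceeding it aborts
#'   with a timeout result.
#' @return A `speller_result` (operations = successful clicks).
#' @examples
#' simulate_scanner("ab", letters[1:10], scan_period = 1, seed = 1)
#' @export
simulate_scanner <- function(text, alphabet = default_alphabet(),
                             scan_period = 1, miss_prob = 0, seed = 1L,
                             max_cycles = 100L) {
  assert_scalar_number(scan_period, "scan_period", 0, strict = TRUE)
  assert_scalar_number(miss_prob, "miss_prob", 0)
  if (miss_prob > 1) stop_invalid_argument("`miss_prob` must be in [0, 1].")
  symbols <- if (nchar(text) > 0) tokenize_text(text, alphabet) else character(0)
  n <- length(alphabet)
  total <- 0; ops <- 0L; misses <- 0L; timeout <- FALSE
  log_rows <- list()
  withr::with_seed(as.integer(seed), {
    for (target in symbols) {
      pos <- match(target, alphabet)
      total <- total + pos * scan_period    # scan reaches the target
      cycles <- 0L
      repeat {
        if (runif(1) >= miss_prob) {        # click recognized
          ops <- ops + 1L
          break
        }
        misses <- misses + 1L
        cycles <- cycles + 1L
        if (cycles >= max_cycles) { timeout <- TRUE; break }
        total <- total + n * scan_period    # wait for the next pass
      }
      log_rows[[length(log_rows) + 1L]] <-
        tibble(symbol = target, position = pos, cycles = cycles)
      if (timeout) break
    }
  })
  log <- if (length(log_rows)) bind_rows(log_rows) else
    tibble(symbol = character(0), position = integer(0), cycles = integer(0))
  new_speller_result(
    total_time = total, operations = ops, misses = misses,
    transcript = if (timeout) "" else paste(symbols, collapse = ""),
    log = log, timeout = timeout
  )
}
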