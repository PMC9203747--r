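#' Read a Boolean network from a file
#'
#' Two formats are supported:
#' \describe{
#'   \item{\code{bnet}}{BoolNet-style rule files: a \code{targets, factors}
#'     header followed by one \code{name, expression} line per node.
#'     Expressions may use \code{!}, \code{&}, \code{|}, parentheses, node
#'     names and the constants \code{0}/\code{1}; \code{#} starts a
#'     comment. Expressions are compiled to truth tables.}
#'   \item{\code{json}}{the canonical lossless schema:
#'     \code{\{"nodes": [...], "rules": [\{"target", "regulators",
#'     "outputs"\}]\}} where \code{outputs} is the truth-table bit string
#'     with the first (lowest-index) regulator as most significant bit.}
#' }
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"bnet"} or
#'   \code{"json"}.
#' @return a \code{\link{boolean_network}}.
#' @export
read_boolean_network <- function(path, format = c("auto", "bnet", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
      else "bnet"
  }
  if (format == "json") {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(spec$nodes) || is.null(spec$rules))
      stop("JSON network must contain `nodes` and `rules`", call. = FALSE)
    nodes <- as.character(spec$nodes)
    rules <- spec$rules
    tgt <- rules$target
    if (anyNA(match(nodes, tgt)) || length(tgt) != length(nodes))
      stop("JSON rules must cover every node exactly once", call. = FALSE)
    ord <- match(nodes, tgt)
    regs <- lapply(rules$regulators[ord], as.character)
    funs <- lapply(rules$outputs[ord], function(s)
      as.integer(strsplit(s, "")[[1L]]))
    return(boolean_network(nodes, regs, funs))
  }
  parse_bnet_lines(readLines(path, warn = FALSE))
}

parse_bnet_lines <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !grepl("^targets\\s*,\\s*factors$", lines[1L],
                               ignore.case = TRUE))
    stop("missing 'targets, factors' header", call. = FALSE)
  lines <- lines[-1L]
  parts <- regmatches(lines, regexpr(",", lines), invert = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("line %d: expected 'target, expression'", bad[1L] + 1L),
         call. = FALSE)
  targets <- trimws(vapply(parts, `[`, "", 1L))
  exprs <- trimws(vapply(parts, `[`, "", 2L))
  if (anyDuplicated(targets))
    stop("duplicated target node", call. = FALSE)
  n <- length(targets)
  regs <- vector("list", n)
  funs <- vector("list", n)
  for (i in seq_len(n)) {
    ast <- parse_bool_expr(exprs[i], line = i + 1L)
    vars <- sort(unique(bool_expr_vars(ast)))
    unknown <- setdiff(vars, targets)
    if (length(unknown))
      stop(sprintf("line %d: unknown node '%s' in rule for '%s'",
                   i + 1L, unknown[1L], targets[i]), call. = FALSE)
    # order regulators by declared node index (the canonical convention)
    vars <- vars[order(match(vars, targets))]
    k <- length(vars)
    if (k > 16L)
      stop(sprintf("rule for '%s' has %d inputs (max 16)", targets[i], k),
           call. = FALSE)
    if (k == 0L) {
      regs[[i]] <- character(0)
      funs[[i]] <- eval_bool_expr(ast, stats::setNames(integer(0),
                                                       character(0)))
      next
    }
    out <- integer(2^k)
    for (row in 0:(2^k - 1L)) {
      env <- stats::setNames(row_to_bits(row, k), vars)
      out[row + 1L] <- eval_bool_expr(ast, env)
    }
    regs[[i]] <- vars
    funs[[i]] <- out
  }
  boolean_network(targets, regs, funs)
}

# --- minimal recursive-descent parser for !, &, |, (), names, 0/1 ---------

tokenize_bool <- function(text, line) {
  pat <- "\\s*([A-Za-z_][A-Za-z0-9_.]*|[01]|[!&|()])"
  toks <- character(0)
  rest <- text
  while (nzchar(trimws(rest))) {
    m <- regmatches(rest, regexec(paste0("^", pat), rest))[[1L]]
    if (length(m) < 2L)
      stop(sprintf("line %d: cannot tokenize near '%s'", line,
                   substr(trimws(rest), 1L, 12L)), call. = FALSE)
    toks <- c(toks, m[2L])
    rest <- substr(rest, nchar(m[1L]) + 1L, nchar(rest))
  }
  toks
}

parse_bool_expr <- function(text, line = NA_integer_) {
  toks <- tokenize_bool(text, line)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[pos - 1L] }
  parse_or <- function() {
    lhs <- parse_and()
    while (identical(peek(), "|")) {
      advance()
      lhs <- list(op = "|", lhs = lhs, rhs = parse_and())
    }
    lhs
  }
  parse_and <- function() {
    lhs <- parse_not()
    while (identical(peek(), "&")) {
      advance()
      lhs <- list(op = "&", lhs = lhs, rhs = parse_not())
    }
    lhs
  }
  parse_not <- function() {
    tok <- peek()
    if (identical(tok, "!")) {
      advance()
      return(list(op = "!", lhs = parse_not()))
    }
    if (identical(tok, "(")) {
      advance()
      e <- parse_or()
      if (!identical(peek(), ")"))
        stop(sprintf("line %d: missing ')'", line), call. = FALSE)
      advance()
      return(e)
    }
    if (is.na(tok))
      stop(sprintf("line %d: unexpected end of expression", line),
           call. = FALSE)
    if (tok %in% c("0", "1")) {
      advance()
      return(list(op = "const", value = as.integer(tok)))
    }
    if (grepl("^[A-Za-z_]", tok)) {
      advance()
      return(list(op = "var", name = tok))
    }
    stop(sprintf("line %d: unexpected token '%s'", line, tok), call. = FALSE)
  }
  e <- parse_or()
  if (pos <= length(toks))
    stop(sprintf("line %d: trailing token '%s'", line, toks[pos]),
         call. = FALSE)
  e
}

bool_expr_vars <- function(ast) {
  switch(ast$op,
         var = ast$name,
         const = character(0),
         "!" = bool_expr_vars(ast$lhs),
         c(bool_expr_vars(ast$lhs), bool_expr_vars(ast$rhs)))
}

eval_bool_expr <- function(ast, env) {
  switch(ast$op,
         var = unname(env[[ast$name]]),
         const = ast$value,
         "!" = 1L - eval_bool_expr(ast$lhs, env),
         "&" = eval_bool_expr(ast$lhs, env) * eval_bool_expr(ast$rhs, env),
         "|" = max(eval_bool_expr(ast$lhs, env),
                   eval_bool_expr(ast$rhs, env)))
}

#' Write a Boolean network to a file
#'
#' The JSON format is lossless (canonical truth tables); writing to
#' \code{bnet} emits a disjunctive-normal-form expression per node. A
#' round trip through JSON reproduces the network exactly.
#'
#' @param net a \code{\link{boolean_network}}.
#' @param path output file path.
#' @param format \code{"auto"} (by extension), \code{"bnet"} or
#'   \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_boolean_network <- function(net, path,
                                  format = c("auto", "bnet", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
      else "bnet"
  if (format == "json") {
    rules <- data.frame(target = net$nodes, stringsAsFactors = FALSE)
    rules$regulators <- lapply(net$regulators, function(r) net$nodes[r])
    rules$outputs <- vapply(net$functions, paste, "", collapse = "")
    jsonlite::write_json(list(nodes = net$nodes, rules = rules), path,
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  lines <- c("targets, factors")
  for (i in seq_along(net$nodes)) {
    r <- net$regulators[[i]]
    out <- net$functions[[i]]
    expr <- if (all(out == 0L)) "0" else if (all(out == 1L)) "1" else {
      k <- length(r)
      terms <- vapply(which(out == 1L) - 1L, function(row) {
        bits <- row_to_bits(row, k)
        paste0(ifelse(bits == 1L, "", "!"), net$nodes[r], collapse = " & ")
      }, "")
      if (length(terms) > 1L)
        paste0("(", terms, ")", collapse = " | ") else terms
    }
    lines <- c(lines, paste0(net$nodes[i], ", ", expr))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Deterministic column order, floats at 12 significant digits.
#'
#' @param x a data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_results_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x))
    if (is.double(x[[j]])) x[[j]] <- signif(x[[j]], 12L)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a greedy trace as JSON
#'
#' @param trace a \code{greedy_trace}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trace_json <- function(trace, path) {
  stopifnot(inherits(trace, "greedy_trace"))
  obj <- list(
    converged = trace$converged,
    constrained = trace$constrained,
    entropy = trace$entropy,
    t_max = trace$t_max,
    epsilon = trace$epsilon,
    stages = trace$stages,
    final_set = data.frame(node = trace$final$nodes,
                           state = trace$final$state))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
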