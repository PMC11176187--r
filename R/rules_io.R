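#' Read and write Boolean networks as plain-text rule files
#'
#' The interchange format is the `.bnet`-style dialect used by public
#' repositories of curated Boolean models: one line per node of the form
#' `target, expression`, where the expression combines regulator names with
#' `&`/`AND`, `|`/`OR`, `!`/`NOT`, parentheses and the constants `0`/`1`.
#' An optional `targets, factors` header line and `#` comments are skipped.
#' Node order in state vectors equals file order. Expressions are compiled to
#' truth tables over the regulators in order of first appearance;
#' `write_rules()` emits a sum-of-products expression per node, and
#' `read_rules(write_rules(net))` reproduces every truth table bit-exactly.
#'
#' @param text a file path, or a character vector of rule lines.
#' @param net a [boolean_network()].
#' @param path optional output file for `write_rules()`.
#' @return `read_rules()`: a [boolean_network()]. `write_rules()`: the rule
#'   lines, invisibly when written to a file.
#' @examples
#' net <- read_rules(c("A, B & !C", "B, A", "C, C"))
#' external_parameters(net)  # C
#' @export
read_rules <- function(text) {
  lines <- if (length(text) == 1 && file.exists(text)) readLines(text) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- lines[tolower(gsub("\\s", "", lines)) != "targets,factors"]
  if (length(lines) == 0) stop("no rule lines found")
  targets <- character(0); exprs <- character(0)
  for (ln in seq_along(lines)) {
    parts <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      stop("parse error on line ", ln, ": expected `target, expression`")
    tgt <- trimws(parts[1])
    if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", tgt))
      stop("parse error on line ", ln, ": invalid target name `", tgt, "`")
    if (tgt %in% targets) stop("duplicate target `", tgt, "` on line ", ln)
    targets <- c(targets, tgt)
    exprs <- c(exprs, trimws(paste(parts[-1], collapse = ",")))
  }
  rules <- vector("list", length(targets))
  regulators <- vector("list", length(targets))
  for (j in seq_along(targets)) {
    comp <- compile_rule_expression(exprs[j], targets, line = j)
    rules[[j]] <- comp$tt
    regulators[[j]] <- comp$regulators
  }
  boolean_network(rules, regulators, node_names = targets)
}

## compile one logical expression into a truth table over its regulators
compile_rule_expression <- function(expr_text, node_names, line = NA) {
  txt <- expr_text
  ## word operators -> R operators (case-insensitive, word-bounded)
  txt <- gsub("\\bAND\\b", "&", txt, ignore.case = TRUE)
  txt <- gsub("\\bOR\\b", "|", txt, ignore.case = TRUE)
  txt <- gsub("\\bNOT\\b", "!", txt, ignore.case = TRUE)
  e <- tryCatch(str2lang(txt),
                error = function(err)
                  stop("parse error on line ", line, ": ", conditionMessage(err)))
  vars <- setdiff(all.vars(e), c("0", "1"))
  bad_calls <- setdiff(all.names(e), c(vars, "&", "|", "!", "(", "&&", "||"))
  if (length(bad_calls))
    stop("parse error on line ", line, ": unsupported operator(s) ",
         paste(unique(bad_calls), collapse = ", "))
  unknown <- setdiff(vars, node_names)
  if (length(unknown))
    stop("line ", line, ": undeclared regulator(s) ",
         paste(unknown, collapse = ", "))
  k <- length(vars)
  X <- tt_inputs(k)
  out <- integer(nrow(X))
  for (r in seq_len(nrow(X))) {
    env <- as.list(as.logical(X[r, ]))
    names(env) <- vars
    val <- eval(e, envir = env, enclos = baseenv())
    out[r] <- as.integer(as.logical(val))
  }
  list(tt = truth_table(out, variable_names = vars),
       regulators = match(vars, node_names))
}

#' @rdname read_rules
#' @export
write_rules <- function(net, path = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  lines <- vapply(seq_len(net$n), function(j) {
    expr <- tt_to_expression(net$rules[[j]],
                             variable_names = net$node_names[net$regulators[[j]]])
    paste0(net$node_names[j], ", ", expr)
  }, character(1))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
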