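# Reader/writer for the Bayesian Interchange Format (BIF 0.15), restricted to
# the subset emitted by the bnlearn repository: network / variable /
# probability blocks, discrete variables only, property lines ignored.
# Parenthesized per-configuration CPT rows; `table` rows for parentless nodes.

bif_tokenize <- function(text) {
  # strip comments
  text <- gsub("//[^\n]*", "", text)
  text <- gsub("/\\*.*?\\*/", "", text, perl = TRUE)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  pat <- "([A-Za-z_][A-Za-z0-9_.-]*|[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?|[{}()\\[\\];,|])"
  toks <- character(0); tlin <- integer(0)
  for (i in seq_along(lines)) {
    m <- gregexpr(pat, lines[i], perl = TRUE)[[1]]
    if (m[1] == -1) next
    got <- regmatches(lines[i], list(m))[[1]]
    toks <- c(toks, got)
    tlin <- c(tlin, rep(i, length(got)))
  }
  list(tok = toks, line = tlin)
}

#' Parse a Bayesian network from BIF text
#'
#' Accepts the discrete-network subset of BIF 0.15 as emitted by the bnlearn
#' network repository: `network`, `variable` and `probability` blocks;
#' `property` lines are ignored. CPT rows are normalized to the package's
#' mixed-radix parent-configuration order (first parent varying fastest).
#'
#' @param text A single string of BIF source, or a character vector of lines.
#' @return A [bayesian_network()].
#' @seealso [read_bif()], [write_bif()]
#' @export
parse_bif <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  tk <- bif_tokenize(text)
  toks <- tk$tok; lins <- tk$line
  pos <- 1L
  n <- length(toks)
  perr <- function(msg, at = pos) {
    l <- if (at <= n) lins[at] else if (n > 0) lins[n] else 0L
    stop(sprintf("BIF parse error at line %d: %s", l, msg), call. = FALSE)
  }
  peek <- function() if (pos <= n) toks[pos] else NA_character_
  nxt <- function() { if (pos > n) perr("unexpected end of input"); t <- toks[pos]; pos <<- pos + 1L; t }
  expect <- function(what) { t <- nxt(); if (t != what) perr(sprintf("expected '%s', got '%s'", what, t), pos - 1L); t }
  skip_property <- function() {           # 'property' ... ';'
    while (pos <= n && toks[pos] != ";") pos <<- pos + 1L
    if (pos > n) perr("unterminated property line")
    pos <<- pos + 1L
  }

  net_name <- NULL
  var_names <- character(0)
  var_arity <- integer(0)
  var_labels <- list()
  prob_parents <- list()
  prob_rows <- list()     # per child: list(parent_labels = list, probs = list) or table

  while (!is.na(peek())) {
    kw <- nxt()
    if (kw == "network") {
      net_name <- nxt()
      expect("{")
      while (!identical(peek(), "}")) {
        if (peek() == "property") skip_property() else nxt()
      }
      expect("}")
    } else if (kw == "variable") {
      vname <- nxt()
      expect("{")
      labs <- NULL; ar <- NA_integer_
      while (!identical(peek(), "}")) {
        t <- nxt()
        if (t == "property") { skip_property(); next }
        if (t == "type") {
          if (nxt() != "discrete") perr("only discrete variables are supported", pos - 1L)
          expect("["); ar <- as.integer(nxt()); expect("]")
          expect("{")
          labs <- character(0)
          repeat {
            labs <- c(labs, nxt())
            t2 <- nxt()
            if (t2 == "}") break
            if (t2 != ",") perr("expected ',' or '}' in value list", pos - 1L)
          }
          expect(";")
          if (length(labs) != ar) perr(sprintf("variable '%s': %d labels but arity %d", vname, length(labs), ar))
        }
      }
      expect("}")
      if (is.na(ar)) perr(sprintf("variable '%s' has no type declaration", vname))
      var_names <- c(var_names, vname)
      var_arity <- c(var_arity, ar)
      var_labels[[vname]] <- labs
    } else if (kw == "probability") {
      expect("(")
      child <- nxt()
      pars <- character(0)
      t <- nxt()
      if (t == "|") {
        repeat {
          pars <- c(pars, nxt())
          t2 <- nxt()
          if (t2 == ")") break
          if (t2 != ",") perr("expected ',' or ')' in parent list", pos - 1L)
        }
      } else if (t != ")") perr("expected '|' or ')'", pos - 1L)
      expect("{")
      rows <- list()
      tabrow <- NULL
      while (!identical(peek(), "}")) {
        t <- nxt()
        if (t == "property") { skip_property(); next }
        if (t == "table") {
          probs <- numeric(0)
          repeat {
            probs <- c(probs, as.numeric(nxt()))
            t2 <- nxt()
            if (t2 == ";") break
            if (t2 != ",") perr("expected ',' or ';' in table row", pos - 1L)
          }
          tabrow <- probs
        } else if (t == "(") {
          labs <- character(0)
          repeat {
            labs <- c(labs, nxt())
            t2 <- nxt()
            if (t2 == ")") break
            if (t2 != ",") perr("expected ',' or ')' in configuration", pos - 1L)
          }
          probs <- numeric(0)
          repeat {
            probs <- c(probs, as.numeric(nxt()))
            t2 <- nxt()
            if (t2 == ";") break
            if (t2 != ",") perr("expected ',' or ';' in probability row", pos - 1L)
          }
          rows[[length(rows) + 1L]] <- list(labels = labs, probs = probs)
        } else perr(sprintf("unexpected token '%s' in probability block", t), pos - 1L)
      }
      expect("}")
      prob_parents[[child]] <- pars
      prob_rows[[child]] <- list(rows = rows, table = tabrow)
    } else perr(sprintf("unexpected top-level token '%s'", kw), pos - 1L)
  }

  if (!length(var_names)) stop("BIF parse error: no variables declared", call. = FALSE)
  names(var_arity) <- var_names
  missing_p <- setdiff(var_names, names(prob_parents))
  if (length(missing_p))
    stop("BIF validation error: no probability block for: ",
         paste(missing_p, collapse = ", "), call. = FALSE)

  parents <- list(); cpts <- list()
  for (v in var_names) {
    pars <- prob_parents[[v]]
    unknown <- setdiff(c(v, pars), var_names)
    if (length(unknown))
      stop("BIF validation error: undeclared variable: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    ar <- var_arity[[v]]
    nconf <- if (length(pars)) prod(var_arity[pars]) else 1L
    cpt <- matrix(NA_real_, nconf, ar)
    pr <- prob_rows[[v]]
    if (!length(pars)) {
      row <- if (!is.null(pr$table)) pr$table
             else if (length(pr$rows) == 1L) pr$rows[[1L]]$probs
             else NULL
      if (is.null(row) || length(row) != ar)
        stop(sprintf("BIF validation error: bad marginal table for '%s'", v), call. = FALSE)
      cpt[1L, ] <- row
    } else {
      if (!length(pr$rows))
        stop(sprintf("BIF validation error: '%s' needs per-configuration rows", v), call. = FALSE)
      for (rw in pr$rows) {
        if (length(rw$labels) != length(pars))
          stop(sprintf("BIF validation error: configuration arity mismatch for '%s'", v), call. = FALSE)
        conf0 <- integer(length(pars))
        for (j in seq_along(pars)) {
          k <- match(rw$labels[j], var_labels[[pars[j]]])
          if (is.na(k))
            stop(sprintf("BIF validation error: unknown value '%s' of '%s'", rw$labels[j], pars[j]), call. = FALSE)
          conf0[j] <- k - 1L
        }
        idx <- encode_cells(matrix(conf0, 1L), var_arity[pars])
        if (length(rw$probs) != ar)
          stop(sprintf("BIF validation error: row length mismatch for '%s'", v), call. = FALSE)
        cpt[idx, ] <- rw$probs
      }
      if (anyNA(cpt))
        stop(sprintf("BIF validation error: missing parent configuration rows for '%s'", v), call. = FALSE)
    }
    if (any(abs(rowSums(cpt) - 1) > 1e-6))
      stop(sprintf("BIF validation error: CPT rows of '%s' do not sum to 1", v), call. = FALSE)
    parents[[v]] <- pars
    cpts[[v]] <- cpt
  }
  bayesian_network(var_names, unname(var_arity), parents, cpts,
                   value_labels = var_labels)
}

#' Read a Bayesian network from a BIF file
#'
#' @param path Path to a `.bif` file.
#' @return A [bayesian_network()].
#' @export
read_bif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_bif(readLines(path, warn = FALSE))
}

#' Serialize a Bayesian network to BIF text
#'
#' Emits the same bnlearn-style subset that [parse_bif()] accepts, so networks
#' round-trip exactly (up to floating-point formatting of probabilities).
#'
#' @param bn A [bayesian_network()].
#' @param path Optional path; when given the text is also written to the file.
#' @return The BIF document as a character string (invisibly when `path` is given).
#' @export
write_bif <- function(bn, path = NULL) {
  fmt <- function(p) sub("0+$", "", sub("\\.?0+$", ".0", sprintf("%.12f", p)))
  out <- c("network unknown {", "}")
  for (v in bn$nodes) {
    out <- c(out,
      sprintf("variable %s {", v),
      sprintf("  type discrete [ %d ] { %s };", bn$arities[[v]],
              paste(bn$value_labels[[v]], collapse = ", ")),
      "}")
  }
  for (v in bn$nodes) {
    pa <- bn$parents[[v]]
    cpt <- bn$cpts[[v]]
    if (!length(pa)) {
      out <- c(out,
        sprintf("probability ( %s ) {", v),
        sprintf("  table %s;", paste(fmt(cpt[1L, ]), collapse = ", ")),
        "}")
    } else {
      hdr <- sprintf("probability ( %s | %s ) {", v, paste(pa, collapse = ", "))
      rows <- character(nrow(cpt))
      ar <- bn$arities[pa]
      for (r in seq_len(nrow(cpt))) {
        rem <- r - 1L
        labs <- character(length(pa))
        for (j in seq_along(pa)) {
          labs[j] <- bn$value_labels[[pa[j]]][rem %% ar[j] + 1L]
          rem <- rem %/% ar[j]
        }
        rows[r] <- sprintf("  (%s) %s;", paste(labs, collapse = ", "),
                           paste(fmt(cpt[r, ]), collapse = ", "))
      }
      out <- c(out, hdr, rows, "}")
    }
  }
  doc <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
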