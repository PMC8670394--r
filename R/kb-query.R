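# Conjunctive description-logic queries over a knowledge base.
#
# Supported class expressions are conjunctions of named classes and
# existential restrictions over named fillers, written in a Manchester-like
# syntax:  `Algorithm and suitableFor some SmallSizeDataset`.

#' Parse a description-logic query string
#'
#' Grammar: `Atom ('and' Atom)*` where an atom is either a named class or
#' `Property some NamedClass`.  Parentheses are permitted around atoms and
#' ignored.  Names are whitespace-free tokens.
#'
#' @param q query string.
#' @return an object of class `dl_query`: a list of atoms, each either
#'   `list(kind = "class", class = ...)` or
#'   `list(kind = "some", prop = ..., class = ...)`.
#' @export
parse_dl_query <- function(q) {
  stopifnot(is.character(q), length(q) == 1L)
  toks <- strsplit(gsub("[()]", " ", q), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("empty query")
  atoms <- list()
  i <- 1L
  repeat {
    if (i > length(toks)) stop("malformed query: dangling 'and'")
    name <- toks[i]
    if (name %in% c("and", "some")) stop("malformed query near '", name, "'")
    if (i + 1L <= length(toks) && toks[i + 1L] == "some") {
      if (i + 2L > length(toks)) stop("malformed query: 'some' without filler")
      atoms[[length(atoms) + 1L]] <- list(kind = "some", prop = name,
                                          class = toks[i + 2L])
      i <- i + 3L
    } else {
      atoms[[length(atoms) + 1L]] <- list(kind = "class", class = name)
      i <- i + 1L
    }
    if (i > length(toks)) break
    if (toks[i] != "and") stop("malformed query near '", toks[i], "'")
    i <- i + 1L
  }
  structure(atoms, class = "dl_query")
}

#' @export
print.dl_query <- function(x, ...) {
  s <- vapply(x, function(a)
    if (a$kind == "class") a$class else paste(a$prop, "some", a$class),
    character(1))
  cat("<dl_query>", paste(s, collapse = " and "), "\n")
  invisible(x)
}

.resolve_query <- function(kb, q) {
  if (is.character(q)) q <- parse_dl_query(q)
  stopifnot(inherits(q, "dl_query"))
  for (a in q) {
    if (!kb_has_entity(kb, a$class))
      stop("unresolvable name in query: ", a$class)
    if (a$kind == "some" && !kb_has_entity(kb, a$prop))
      stop("unresolvable name in query: ", a$prop)
  }
  q
}

#' Answer a description-logic query
#'
#' Returns every named class subsumed by all conjuncts, plus every individual
#' satisfying them, over the classified knowledge base.  A class X satisfies a
#' named-class atom C when X is (reflexively-transitively) a subclass of C; it
#' satisfies `P some C` when some existential restriction `X' <= P' some C'`
#' exists with X a subclass of X', P' a subproperty of P, and C' a subclass of
#' C.  An individual satisfies atoms through its class assertions and
#' object-property assertions.  The answer is sorted lexicographically, so it
#' is deterministic and order-independent.
#'
#' @param kb a knowledge base.
#' @param q a query string or a parsed [parse_dl_query()] object.
#' @param closure optional precomputed [kb_classify()] result.
#' @return sorted character vector of entity local names.
#' @export
kb_query <- function(kb, q, closure = NULL) {
  q <- .resolve_query(kb, q)
  if (is.null(closure)) closure <- kb_classify(kb)
  canc <- closure$class_anc
  panc <- closure$prop_anc
  res <- kb$axioms[kb$axioms$type == "RESTRICTION", , drop = FALSE]
  typ <- kb$axioms[kb$axioms$type == "TYPE", , drop = FALSE]
  prp <- kb$axioms[kb$axioms$type == "PROP", , drop = FALSE]

  class_sat <- function(x, atom) {
    if (atom$kind == "class") return(atom$class %in% canc[[x]])
    # some(P, C): restriction on an ancestor of x, property below P, filler below C
    ok <- res$s %in% canc[[x]] &
      vapply(res$p, function(p) atom$prop %in% panc[[p]], logical(1)) &
      vapply(res$o, function(o) atom$class %in% canc[[o]], logical(1))
    any(ok)
  }
  ind_sat <- function(x, atom) {
    if (atom$kind == "class") {
      cls <- typ$o[typ$s == x]
      return(any(vapply(cls, function(cc) atom$class %in% canc[[cc]], logical(1))))
    }
    rows <- prp[prp$s == x, , drop = FALSE]
    if (!nrow(rows)) return(FALSE)
    any(vapply(seq_len(nrow(rows)), function(i) {
      if (!(atom$prop %in% panc[[rows$p[i]]])) return(FALSE)
      cls <- typ$o[typ$s == rows$o[i]]
      any(vapply(cls, function(cc) atom$class %in% canc[[cc]], logical(1)))
    }, logical(1)))
  }

  cls_ans <- Filter(function(x) all(vapply(q, function(a) class_sat(x, a), logical(1))),
                    kb_classes(kb))
  ind_ans <- Filter(function(x) all(vapply(q, function(a) ind_sat(x, a), logical(1))),
                    kb_individuals(kb))
  sort(unique(c(unlist(cls_ans), unlist(ind_ans))), method = "radix")
}

#' Fillers of a property restriction on a class
#'
#' Definition lookup: the named fillers C such that `cls <= prop some C`,
#' taking inherited restrictions (on superclasses of `cls`) and subproperties
#' of `prop` into account.
#'
#' @param kb a knowledge base.
#' @param cls class local name.
#' @param prop object-property local name.
#' @param closure optional precomputed closure.
#' @return sorted character vector of filler class names.
#' @export
kb_fillers <- function(kb, cls, prop, closure = NULL) {
  if (!kb_has_entity(kb, cls)) stop("unresolvable name: ", cls)
  if (is.null(closure)) closure <- kb_classify(kb)
  res <- kb$axioms[kb$axioms$type == "RESTRICTION", , drop = FALSE]
  keep <- res$s %in% closure$class_anc[[cls]] &
    vapply(res$p, function(p) prop %in% closure$prop_anc[[p]], logical(1))
  sort(unique(res$o[keep]), method = "radix")
}

#' Data-property values of an entity
#'
#' @param kb a knowledge base.
#' @param subject entity local name (class or individual).
#' @param prop data-property local name.
#' @return character vector of literal values (with a `datatype` attribute
#'   when a single value is returned).
#' @export
kb_data_values <- function(kb, subject, prop) {
  dpr <- kb$axioms[kb$axioms$type == "DATAPROP", , drop = FALSE]
  hit <- dpr[dpr$s == subject & dpr$p == prop, , drop = FALSE]
  v <- hit$v
  if (length(v) == 1L) attr(v, "datatype") <- hit$dt
  v
}
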