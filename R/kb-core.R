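# Knowledge bases as typed entity/axiom graphs.
#
# A knowledge base is the five-tuple (C, R, H^C, H^R, I): concepts C and
# properties R with their subsumption hierarchies H^C (subClassOf) and H^R
# (subPropertyOf), plus instantiation assertions I.  Axioms are stored as a
# flat table, one row per assertion, in six forms:
#
#   SUBCLASSOF  C1 C2            C1 is a subclass of C2
#   SUBPROP     R1 R2            R1 is a subproperty of R2
#   RESTRICTION C1 P some C2     C1 is subsumed by the existential P-restriction on C2
#   TYPE        i  C             individual i is an instance of class C
#   PROP        i  P  j          object-property assertion between individuals
#   DATAPROP    s  D  value dt   data-property assertion with a typed literal
#
# Entities carry a namespace (shared per KB) and a local name; axioms refer to
# entities by local name.

AXIOM_TYPES <- c("SUBCLASSOF", "SUBPROP", "RESTRICTION", "TYPE", "PROP", "DATAPROP")
ENTITY_KINDS <- c("class", "object-property", "data-property", "individual")

empty_axioms <- function() {
  data.frame(type = character(), s = character(), p = character(),
             o = character(), v = character(), dt = character(),
             stringsAsFactors = FALSE)
}

#' Construct an axiom table
#'
#' Convenience builder used by the packaged knowledge bases and by tests.
#' Each argument is a character matrix-like specification of one axiom form.
#'
#' @param subclass two-column matrix or vector pairs `c(C1, C2)`: C1 subClassOf C2.
#' @param subprop two-column pairs `c(R1, R2)`: R1 subPropertyOf R2.
#' @param restriction three-column triples `c(C1, P, C2)`: C1 subsumed by "P some C2".
#' @param type two-column pairs `c(i, C)`: class assertion.
#' @param prop three-column triples `c(i, P, j)`: object-property assertion.
#' @param dataprop four-column rows `c(s, D, value, datatype)`.
#' @return an axiom `data.frame` suitable for [knowledge_base()].
#' @export
axiom_table <- function(subclass = NULL, subprop = NULL, restriction = NULL,
                        type = NULL, prop = NULL, dataprop = NULL) {
  rows <- list()
  as_mat <- function(x, k) {
    if (is.null(x)) return(NULL)
    m <- matrix(as.character(t(x)), ncol = k, byrow = TRUE)
    m
  }
  add <- function(ty, m, cols) {
    if (is.null(m) || nrow(m) == 0) return()
    df <- empty_axioms()[rep(1L, 0), ]
    df <- data.frame(type = rep(ty, nrow(m)), s = NA_character_, p = NA_character_,
                     o = NA_character_, v = NA_character_, dt = NA_character_,
                     stringsAsFactors = FALSE)
    for (j in seq_along(cols)) df[[cols[j]]] <- m[, j]
    rows[[length(rows) + 1L]] <<- df
  }
  add("SUBCLASSOF", as_mat(subclass, 2L), c("s", "o"))
  add("SUBPROP", as_mat(subprop, 2L), c("s", "o"))
  add("RESTRICTION", as_mat(restriction, 3L), c("s", "p", "o"))
  add("TYPE", as_mat(type, 2L), c("s", "o"))
  add("PROP", as_mat(prop, 3L), c("s", "p", "o"))
  add("DATAPROP", as_mat(dataprop, 4L), c("s", "p", "v", "dt"))
  if (length(rows) == 0) return(empty_axioms())
  do.call(rbind, rows)
}

# Kind constraints implied by each axiom form.  DATAPROP subjects are
# deliberately unconstrained: data properties may annotate classes (threshold
# definitions such as a minimum series length) as well as individuals.
.axiom_kind_constraints <- function(ax) {
  out <- list()
  push <- function(name, kind) {
    name <- name[!is.na(name) & nzchar(name)]
    if (length(name)) out[[length(out) + 1L]] <<- data.frame(
      name = name, kind = kind, stringsAsFactors = FALSE)
  }
  sel <- function(ty) ax[ax$type == ty, , drop = FALSE]
  a <- sel("SUBCLASSOF"); push(c(a$s, a$o), "class")
  a <- sel("SUBPROP");    push(c(a$s, a$o), "object-property")
  a <- sel("RESTRICTION"); push(c(a$s, a$o), "class"); push(a$p, "object-property")
  a <- sel("TYPE");       push(a$s, "individual"); push(a$o, "class")
  a <- sel("PROP");       push(c(a$s, a$o), "individual"); push(a$p, "object-property")
  a <- sel("DATAPROP");   push(a$p, "data-property")
  if (length(out) == 0) return(data.frame(name = character(), kind = character()))
  unique(do.call(rbind, out))
}

#' Create a knowledge base
#'
#' Builds a validated knowledge base from an axiom table.  Entity kinds are
#' inferred from the axiom forms they appear in; entities that occur in no
#' axiom (isolated classes, unused properties) can be declared explicitly.
#'
#' @param axioms axiom `data.frame` as produced by [axiom_table()].
#' @param declare optional `data.frame` with columns `name`, `kind` declaring
#'   entities not mentioned by any axiom.
#' @param namespace namespace string prefixed (conceptually) to every local
#'   name to form the entity IRI.
#' @return an object of class `knowledge_base` with fields `namespace`,
#'   `entities` (`data.frame` of `name`, `kind`) and `axioms`.
#' @export
knowledge_base <- function(axioms = empty_axioms(), declare = NULL, namespace = "kb") {
  stopifnot(is.data.frame(axioms))
  if (nrow(axioms) && !all(axioms$type %in% AXIOM_TYPES))
    stop("unknown axiom type: ", paste(setdiff(axioms$type, AXIOM_TYPES), collapse = ", "))
  kinds <- .axiom_kind_constraints(axioms)
  # DATAPROP subjects default to individuals unless some other axiom fixes a kind
  dp_subj <- setdiff(axioms$s[axioms$type == "DATAPROP"], kinds$name)
  if (length(dp_subj))
    kinds <- rbind(kinds, data.frame(name = unique(dp_subj), kind = "individual"))
  if (!is.null(declare) && nrow(declare)) {
    stopifnot(all(c("name", "kind") %in% names(declare)),
              all(declare$kind %in% ENTITY_KINDS))
    kinds <- unique(rbind(kinds, declare[, c("name", "kind")]))
  }
  dup <- kinds$name[duplicated(kinds$name)]
  if (length(dup)) {
    d <- dup[1L]
    stop(sprintf("entity kind conflict for '%s': declared both %s", d,
                 paste(sort(kinds$kind[kinds$name == d]), collapse = " and ")))
  }
  kinds <- kinds[order(kinds$name, method = "radix"), , drop = FALSE]
  rownames(kinds) <- NULL
  rownames(axioms) <- NULL
  structure(list(namespace = namespace, entities = kinds, axioms = axioms),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base> namespace '%s': %d entities, %d axioms\n",
              x$namespace, nrow(x$entities), nrow(x$axioms)))
  if (nrow(x$entities)) {
    tab <- table(x$entities$kind)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of entities / axioms
#' @param kb a knowledge base.
#' @return integer count.
#' @export
kb_n_entities <- function(kb) nrow(kb$entities)

#' @rdname kb_n_entities
#' @export
kb_n_axioms <- function(kb) nrow(kb$axioms)

#' Does the KB contain an entity?
#' @param kb a knowledge base.
#' @param name local entity name.
#' @return logical.
#' @export
kb_has_entity <- function(kb, name) name %in% kb$entities$name

kb_entity_kind <- function(kb, name) {
  k <- kb$entities$kind[match(name, kb$entities$name)]
  k
}

kb_classes <- function(kb) kb$entities$name[kb$entities$kind == "class"]
kb_individuals <- function(kb) kb$entities$name[kb$entities$kind == "individual"]

# canonical ordering of an axiom table, for set/multiset comparison
kb_canonical_axioms <- function(kb) {
  ax <- kb$axioms
  key <- do.call(paste, c(lapply(ax, function(c) ifelse(is.na(c), "", c)), sep = "\t"))
  ax <- ax[order(key, method = "radix"), , drop = FALSE]
  rownames(ax) <- NULL
  ax
}

#' Read a knowledge base from its tab-separated axiom file
#'
#' The file format is UTF-8 text, one axiom per line, fields separated by
#' tabs: `SUBCLASSOF C1 C2`, `SUBPROP R1 R2`, `RESTRICTION C1 P some C2`,
#' `TYPE i C`, `PROP i P j`, `DATAPROP s D value datatype`, plus
#' `DECLARE kind name` for entities that occur in no axiom.  Lines starting
#' with `#` and blank lines are ignored.
#'
#' @param path file path.
#' @param namespace namespace for the loaded KB; defaults to the file name
#'   without extension.
#' @return a `knowledge_base`.
#' @export
read_kb <- function(path, namespace = NULL) {
  if (!file.exists(path)) stop("KB file not found: ", path)
  if (is.null(namespace)) namespace <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  rows <- list(); decls <- list()
  for (i in idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    ty <- f[1]
    bad <- function() stop(sprintf("parse error at line %d: malformed %s axiom", i, ty))
    row <- switch(ty,
      SUBCLASSOF = { if (length(f) != 3) bad(); axiom_table(subclass = f[2:3]) },
      SUBPROP    = { if (length(f) != 3) bad(); axiom_table(subprop = f[2:3]) },
      RESTRICTION = {
        if (length(f) != 5 || f[4] != "some") bad()
        axiom_table(restriction = f[c(2, 3, 5)])
      },
      TYPE = { if (length(f) != 3) bad(); axiom_table(type = f[2:3]) },
      PROP = { if (length(f) != 4) bad(); axiom_table(prop = f[2:4]) },
      DATAPROP = { if (length(f) != 5) bad(); axiom_table(dataprop = f[2:5]) },
      DECLARE = {
        if (length(f) != 3 || !(f[2] %in% ENTITY_KINDS))
          stop(sprintf("parse error at line %d: malformed DECLARE", i))
        decls[[length(decls) + 1L]] <- data.frame(name = f[3], kind = f[2],
                                                  stringsAsFactors = FALSE)
        NULL
      },
      stop(sprintf("parse error at line %d: unknown axiom type '%s'", i, ty))
    )
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  ax <- if (length(rows)) do.call(rbind, rows) else empty_axioms()
  decl <- if (length(decls)) do.call(rbind, decls) else NULL
  kb <- knowledge_base(ax, declare = decl, namespace = namespace)
  .check_acyclic(kb)
  kb
}

#' Write a knowledge base to the tab-separated axiom file format
#'
#' Inverse of [read_kb()]: writing then reading reproduces the same entity
#' set and axiom multiset.
#'
#' @param kb a knowledge base.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  ax <- kb$axioms
  fmt <- character(nrow(ax))
  for (i in seq_len(nrow(ax))) {
    r <- ax[i, ]
    fmt[i] <- switch(r$type,
      SUBCLASSOF = paste("SUBCLASSOF", r$s, r$o, sep = "\t"),
      SUBPROP = paste("SUBPROP", r$s, r$o, sep = "\t"),
      RESTRICTION = paste("RESTRICTION", r$s, r$p, "some", r$o, sep = "\t"),
      TYPE = paste("TYPE", r$s, r$o, sep = "\t"),
      PROP = paste("PROP", r$s, r$p, r$o, sep = "\t"),
      DATAPROP = paste("DATAPROP", r$s, r$p, r$v, r$dt, sep = "\t"))
  }
  mentioned <- unique(stats::na.omit(c(ax$s, ax$p, ax$o)))
  lone <- kb$entities[!(kb$entities$name %in% mentioned), , drop = FALSE]
  decl <- if (nrow(lone)) paste("DECLARE", lone$kind, lone$name, sep = "\t") else character()
  writeLines(c(decl, fmt), path, useBytes = TRUE)
  invisible(path)
}

# ---- subsumption -----------------------------------------------------------

.edges <- function(kb, type) {
  a <- kb$axioms[kb$axioms$type == type, c("s", "o"), drop = FALSE]
  unique(a)
}

# detect a cycle in the subclass graph; returns NULL or a vector naming it
.find_cycle <- function(edges, nodes) {
  adj <- split(edges$o, factor(edges$s, levels = nodes))
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  stack <- character()
  cyc <- NULL
  visit <- function(v) {
    if (!is.null(cyc)) return()
    color[v] <<- 1L
    stack <<- c(stack, v)
    for (w in adj[[v]]) {
      if (is.null(cyc) && color[w] == 1L) {
        cyc <<- c(stack[which(stack == w)[1]:length(stack)], w)
      } else if (is.null(cyc) && color[w] == 0L) visit(w)
    }
    stack <<- stack[-length(stack)]
    color[v] <<- 2L
  }
  for (v in nodes) if (color[v] == 0L) visit(v)
  cyc
}

.check_acyclic <- function(kb) {
  cyc <- .find_cycle(.edges(kb, "SUBCLASSOF"), kb_classes(kb))
  if (!is.null(cyc))
    stop("cycle detected in subclass hierarchy: ", paste(cyc, collapse = " -> "))
  invisible(TRUE)
}

#' Subsumption closure of a knowledge base
#'
#' Computes the reflexive-transitive closure of the subclass and subproperty
#' hierarchies — the classification step a reasoner performs before query
#' answering.  The closure is idempotent: classifying an already materialized
#' closure changes nothing.
#'
#' @param kb a knowledge base.
#' @return an object of class `kb_closure`: named lists `class_anc` and
#'   `prop_anc` mapping each class/property to the sorted vector of its
#'   ancestors (itself included).
#' @export
kb_classify <- function(kb) {
  .check_acyclic(kb)
  closure_of <- function(nodes, edges) {
    adj <- split(edges$o, factor(edges$s, levels = nodes))
    anc <- stats::setNames(vector("list", length(nodes)), nodes)
    visit <- function(v) {
      if (!is.null(anc[[v]])) return(anc[[v]])
      anc[[v]] <<- v  # mark (acyclic, so no re-entry)
      up <- unique(unlist(lapply(adj[[v]], visit), use.names = FALSE))
      anc[[v]] <<- sort(unique(c(v, up)), method = "radix")
      anc[[v]]
    }
    for (v in nodes) visit(v)
    anc
  }
  structure(list(
    class_anc = closure_of(kb_classes(kb), .edges(kb, "SUBCLASSOF")),
    prop_anc = closure_of(
      kb$entities$name[kb$entities$kind == "object-property"],
      .edges(kb, "SUBPROP"))),
    class = "kb_closure")
}

#' @export
print.kb_closure <- function(x, ...) {
  cat(sprintf("<kb_closure> %d classes, %d properties\n",
              length(x$class_anc), length(x$prop_anc)))
  invisible(x)
}

# all subsumption pairs (sub, super) implied by a closure, as a data.frame
closure_pairs <- function(cl) {
  subs <- rep(names(cl$class_anc), lengths(cl$class_anc))
  data.frame(sub = subs, super = unlist(cl$class_anc, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# ---- merging ---------------------------------------------------------------

#' Merge two knowledge bases
#'
#' Collects the axioms of both inputs and rewrites every entity IRI into a
#' new shared namespace.  Entities with the same local name unify into one
#' entity (the mechanism that connects domain knowledge to data-mining
#' knowledge through shared names); the same local name with two different
#' kinds is a unification conflict.  Byte-identical duplicate axioms are
#' stored once.
#'
#' @param kb_a,kb_b knowledge bases.
#' @param namespace namespace of the merged KB.
#' @return the merged `knowledge_base`.
#' @export
kb_merge <- function(kb_a, kb_b, namespace = "merged") {
  both <- rbind(kb_a$entities, kb_b$entities)
  both <- unique(both)
  dup <- both$name[duplicated(both$name)]
  if (length(dup)) {
    d <- dup[1L]
    stop(sprintf(
      "unification conflict: '%s' is a %s in <%s#%s> but a %s in <%s#%s>",
      d, kb_a$entities$kind[match(d, kb_a$entities$name)], kb_a$namespace, d,
      kb_b$entities$kind[match(d, kb_b$entities$name)], kb_b$namespace, d))
  }
  ax <- unique(rbind(kb_a$axioms, kb_b$axioms))
  knowledge_base(ax, declare = both, namespace = namespace)
}

# ---- sub-ontology extraction ----------------------------------------------

#' Extract the task-related sub-ontology
#'
#' Restriction-path extraction: starting from a task entity, the kept entity
#' set is closed under (i) subclass and subproperty edges taken upward,
#' (ii) existential-restriction axioms crossed in either direction (subject
#' to filler or filler to subject, picking up the property), and
#' (iii) instance assertions of kept classes together with the property and
#' data-property assertions among kept individuals, iterated to a fixed
#' point.  The result keeps exactly the axioms whose full signature lies
#' inside the kept entity set, so it is a sub-KB of the input and the
#' operation is idempotent.
#'
#' @param kb a knowledge base.
#' @param task local name of the task entity to seed from.
#' @return a `knowledge_base` restricted to the entities reachable from
#'   `task`.
#' @export
kb_extract <- function(kb, task) {
  if (!kb_has_entity(kb, task)) stop("unknown task entity: ", task)
  ax <- kb$axioms
  sub <- ax[ax$type == "SUBCLASSOF", , drop = FALSE]
  spr <- ax[ax$type == "SUBPROP", , drop = FALSE]
  res <- ax[ax$type == "RESTRICTION", , drop = FALSE]
  typ <- ax[ax$type == "TYPE", , drop = FALSE]
  prp <- ax[ax$type == "PROP", , drop = FALSE]
  dpr <- ax[ax$type == "DATAPROP", , drop = FALSE]
  kept <- task
  repeat {
    new <- c(
      sub$o[sub$s %in% kept],                      # superclasses
      spr$o[spr$s %in% kept],                      # superproperties
      unlist(res[res$s %in% kept | res$o %in% kept, c("s", "p", "o")]),
      typ$s[typ$o %in% kept],                      # instances of kept classes
      prp$p[prp$s %in% kept & prp$o %in% kept],
      dpr$p[dpr$s %in% kept]
    )
    new <- setdiff(unique(new), kept)
    if (!length(new)) break
    kept <- c(kept, new)
  }
  keep_row <- vapply(seq_len(nrow(ax)), function(i) {
    sig <- stats::na.omit(unlist(ax[i, c("s", "p", "o")], use.names = FALSE))
    all(sig %in% kept)
  }, logical(1))
  decl <- kb$entities[kb$entities$name %in% kept, , drop = FALSE]
  knowledge_base(ax[keep_row, , drop = FALSE], declare = decl,
                 namespace = kb$namespace)
}
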