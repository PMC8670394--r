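# Random knowledge-base generators and independent oracles for the KB engine.

# random KB: subclass edges only from higher to lower class index (acyclic by
# construction), random subproperty edges, restrictions, and individuals
random_kb <- function(n_classes = 10, n_props = 3, n_sub = 12, n_res = 6,
                      n_ind = 0, n_type = 0, n_prop_ax = 0, namespace = "rnd") {
  cls <- paste0("C", seq_len(n_classes))
  prp <- paste0("P", seq_len(n_props))
  sub <- NULL
  if (n_sub > 0 && n_classes > 1) {
    lo <- sample.int(n_classes - 1, n_sub, replace = TRUE)
    hi <- lo + sample.int(n_classes - 1, n_sub, replace = TRUE)
    hi <- pmin(hi, n_classes)
    keep <- hi > lo
    sub <- unique(cbind(cls[hi[keep]], cls[lo[keep]]))  # child = higher index
  }
  res <- if (n_res > 0) cbind(sample(cls, n_res, TRUE), sample(prp, n_res, TRUE),
                              sample(cls, n_res, TRUE)) else NULL
  spr <- if (n_props > 1) unique(cbind(prp[pmax(2, sample.int(n_props, 2, TRUE))],
                                       prp[1])) else NULL
  ind <- if (n_ind > 0) paste0("i", seq_len(n_ind)) else character()
  typ <- if (n_type > 0 && n_ind > 0)
    cbind(sample(ind, n_type, TRUE), sample(cls, n_type, TRUE)) else NULL
  pax <- if (n_prop_ax > 0 && n_ind > 1)
    cbind(sample(ind, n_prop_ax, TRUE), sample(prp, n_prop_ax, TRUE),
          sample(ind, n_prop_ax, TRUE)) else NULL
  knowledge_base(axiom_table(subclass = sub, subprop = spr, restriction = res,
                             type = typ, prop = pax),
                 namespace = namespace)
}

# independent reflexive-transitive closure by boolean matrix powers
closure_matrix_oracle <- function(nodes, edges) {
  n <- length(nodes)
  A <- diag(n) > 0
  dimnames(A) <- list(nodes, nodes)
  for (k in seq_len(nrow(edges))) A[edges$s[k], edges$o[k]] <- TRUE
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  A
}

kb_subclass_edges <- function(kb) {
  a <- kb$axioms[kb$axioms$type == "SUBCLASSOF", c("s", "o"), drop = FALSE]
  unique(a)
}

# independent breadth-first reachability over the documented extraction edge
# relation (subclass/subproperty up, restrictions both ways, instances of
# kept classes, properties among kept entities)
extract_bfs_oracle <- function(kb, seed_entity) {
  ax <- kb$axioms
  kept <- seed_entity
  queue <- seed_entity
  neighbours <- function(set) {
    out <- character()
    for (i in seq_len(nrow(ax))) {
      r <- ax[i, ]
      out <- c(out, switch(r$type,
        SUBCLASSOF = if (r$s %in% set) r$o,
        SUBPROP = if (r$s %in% set) r$o,
        RESTRICTION = if (r$s %in% set || r$o %in% set) c(r$s, r$p, r$o),
        TYPE = if (r$o %in% set) r$s,
        PROP = if (r$s %in% set && r$o %in% set) r$p,
        DATAPROP = if (r$s %in% set) r$p,
        NULL))
    }
    unique(out)
  }
  repeat {
    new <- setdiff(neighbours(kept), kept)
    if (!length(new)) break
    kept <- c(kept, new)
  }
  sort(kept, method = "radix")
}

# direct brute-force evaluation of the documented query semantics, built on
# the matrix-power closure rather than the engine's DFS closure
query_bruteforce_oracle <- function(kb, q) {
  if (is.character(q)) q <- parse_dl_query(q)
  cls <- kb$entities$name[kb$entities$kind == "class"]
  prp <- kb$entities$name[kb$entities$kind == "object-property"]
  ind <- kb$entities$name[kb$entities$kind == "individual"]
  Ccl <- closure_matrix_oracle(cls, kb_subclass_edges(kb))
  Pcl <- closure_matrix_oracle(prp, unique(
    kb$axioms[kb$axioms$type == "SUBPROP", c("s", "o"), drop = FALSE]))
  res <- kb$axioms[kb$axioms$type == "RESTRICTION", , drop = FALSE]
  typ <- kb$axioms[kb$axioms$type == "TYPE", , drop = FALSE]
  pax <- kb$axioms[kb$axioms$type == "PROP", , drop = FALSE]
  cls_sat <- function(x, atom) {
    if (atom$kind == "class") return(Ccl[x, atom$class])
    hit <- FALSE
    for (i in seq_len(nrow(res)))
      if (Ccl[x, res$s[i]] && Pcl[res$p[i], atom$prop] && Ccl[res$o[i], atom$class])
        hit <- TRUE
    hit
  }
  ind_sat <- function(x, atom) {
    if (atom$kind == "class") {
      for (i in seq_len(nrow(typ)))
        if (typ$s[i] == x && Ccl[typ$o[i], atom$class]) return(TRUE)
      return(FALSE)
    }
    for (i in seq_len(nrow(pax)))
      if (pax$s[i] == x && Pcl[pax$p[i], atom$prop])
        for (j in seq_len(nrow(typ)))
          if (typ$s[j] == pax$o[i] && Ccl[typ$o[j], atom$class]) return(TRUE)
    FALSE
  }
  ans <- c(Filter(function(x) all(vapply(q, function(a) cls_sat(x, a), logical(1))), cls),
           Filter(function(x) all(vapply(q, function(a) ind_sat(x, a), logical(1))), ind))
  sort(unique(unlist(ans)), method = "radix")
}

# random well-formed 1- or 2-conjunct query over a KB's vocabulary
random_query <- function(kb, n_conj = 2) {
  cls <- kb$entities$name[kb$entities$kind == "class"]
  prp <- kb$entities$name[kb$entities$kind == "object-property"]
  atom <- function() {
    if (length(prp) && stats::runif(1) < 0.5)
      paste(sample(prp, 1), "some", sample(cls, 1))
    else sample(cls, 1)
  }
  paste(vapply(seq_len(n_conj), function(i) atom(), character(1)), collapse = " and ")
}
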