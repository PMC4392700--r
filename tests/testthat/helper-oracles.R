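# Independent oracles and random-instance generators used across the suite.
# Everything here is written naively (per-fact loops, no shared code with the
# package internals) so it can serve as a cross-check.

# ---- naive view-extraction oracle (two-phase BFS with plain loops) ----

oracle_extract_view <- function(graph, config) {
  tr <- graph$triples
  if (length(config$seeds) == 0) {
    return(list(entities = character(),
                triples = tr[0, , drop = FALSE]))
  }
  grow <- function(members, preds) {
    repeat {
      added <- FALSE
      for (r in seq_len(nrow(tr))) {
        if (tr$predicate[r] %in% preds && tr$subject[r] %in% members &&
            !(tr$object[r] %in% members)) {
          members <- c(members, tr$object[r])
          added <- TRUE
        }
      }
      if (!added) break
    }
    members
  }
  members <- grow(config$seeds, config$follow_properties)
  if (config$lateral_policy == "one_step") {
    newcomers <- character()
    for (r in seq_len(nrow(tr))) {
      if (tr$predicate[r] %in% config$lateral_properties) {
        if (tr$subject[r] %in% members && !(tr$object[r] %in% members))
          newcomers <- c(newcomers, tr$object[r])
        if (tr$object[r] %in% members && !(tr$subject[r] %in% members))
          newcomers <- c(newcomers, tr$subject[r])
      }
    }
    members <- grow(unique(c(members, newcomers)), config$follow_properties)
  }
  if (config$superclass_closure)
    members <- grow(members, "rdfs:subClassOf")
  members <- setdiff(members, union(intersect(graph$metaclasses, members),
                                    config$exclusions))
  keep_pred <- unique(c("rdfs:subClassOf", config$keep_properties,
                        config$lateral_properties))
  keep <- logical(nrow(tr))
  for (r in seq_len(nrow(tr))) {
    keep[r] <- tr$predicate[r] %in% keep_pred &&
      tr$subject[r] %in% members && tr$object[r] %in% members
  }
  list(entities = sort(unique(members)), triples = tr[keep, , drop = FALSE])
}

random_frame_graph <- function(seed) {
  set.seed(seed)
  n <- sample(5:14, 1)
  ents <- paste0("fma:E", seq_len(n))
  t3 <- function(s, p, o) data.frame(subject = s, predicate = p, object = o,
                                     stringsAsFactors = FALSE)
  tri <- list()
  add_random <- function(pred, m) {
    for (i in seq_len(m)) {
      pair <- sample(ents, 2)
      tri[[length(tri) + 1L]] <<- t3(pair[1], pred, pair[2])
    }
  }
  add_random("fma:regional_part_of", sample(2:8, 1))
  add_random("fma:constitutional_part_of", sample(0:4, 1))
  add_random("rdfs:subClassOf", sample(0:5, 1))
  add_random("fma:attributed_continuous_with", sample(0:3, 1))
  add_random("fma:bounded_by", sample(0:2, 1))
  frame_graph(entities = ents, triples = do.call(rbind, tri),
              metaclasses = sample(ents, sample(0:2, 1)))
}

random_extraction_config <- function(graph, seed) {
  set.seed(seed + 77)
  extraction_config(
    seeds = sample(graph$entities, sample(1:3, 1)),
    lateral_policy = sample(c("one_step", "closed"), 1),
    exclusions = if (stats::runif(1) < 0.5) sample(graph$entities, 1) else character(),
    superclass_closure = stats::runif(1) < 0.8)
}

# ---- naive saturation oracle (apply every rule until nothing changes) ----

new_set <- function() {
  e <- new.env(parent = emptyenv())
  e$items <- list()
  e$keys <- character()
  e
}
s_add <- function(s, x) {
  k <- paste(x, collapse = "|")
  if (k %in% s$keys) return(invisible(FALSE))
  s$items[[length(s$items) + 1L]] <- x
  s$keys <- c(s$keys, k)
  invisible(TRUE)
}
s_has <- function(s, x) paste(x, collapse = "|") %in% s$keys
s_size <- function(s) length(s$items)

oracle_saturate <- function(k) {
  tb <- k$tbox
  ab <- k$abox
  pn <- names(tb$properties)
  # property hierarchy, reflexive-transitive, naive
  psup <- stats::setNames(as.list(pn), pn)
  repeat {
    changed <- FALSE
    for (p in pn) {
      for (q in psup[[p]]) {
        for (r in tb$properties[[q]]$super_properties) {
          if (!r %in% psup[[p]]) {
            psup[[p]] <- c(psup[[p]], r)
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  inv <- lapply(tb$properties, function(p) p$inverse)
  trans <- pn[vapply(tb$properties, function(p) p$transitive, TRUE)]

  subs <- new_set()   # pairs c(sub, super)
  cex <- new_set()    # triples c(class, property, filler)
  for (cl in tb$classes) s_add(subs, c(cl, cl))
  decomp <- function(lhs, e) {
    if (e$variant == "named") {
      s_add(subs, c(lhs, e$term))
    } else if (e$variant == "some" && e$filler$variant == "named") {
      s_add(cex, c(lhs, e$property, e$filler$term))
    } else if (e$variant == "and") {
      for (ch in e$children) decomp(lhs, ch)
    }
  }
  for (ax in c(tb$subclass_axioms, tb$equivalence_axioms)) decomp(ax$lhs, ax$rhs)

  sub_in <- function(a, b) s_has(subs, c(a, b))
  class_sat <- function(x, e) {
    switch(e$variant,
      named = sub_in(x, e$term),
      and = all(vapply(e$children, function(ch) class_sat(x, ch), TRUE)),
      or = any(vapply(e$children, function(ch) class_sat(x, ch), TRUE)),
      some = any(vapply(cex$items, function(f)
        f[1] == x && f[2] == e$property && class_sat(f[3], e$filler), TRUE))
    )
  }
  repeat {
    n0 <- s_size(subs) + s_size(cex)
    for (a in subs$items) for (b in subs$items)
      if (a[2] == b[1]) s_add(subs, c(a[1], b[2]))
    for (f in cex$items) for (q in psup[[f[2]]])
      s_add(cex, c(f[1], q, f[3]))
    for (p in trans) for (f in cex$items) for (g in cex$items)
      if (f[2] == p && g[2] == p && f[3] == g[1])
        s_add(cex, c(f[1], p, g[3]))
    for (f in cex$items) for (b in subs$items)
      if (f[3] == b[1]) s_add(cex, c(f[1], f[2], b[2]))
    for (ax in tb$equivalence_axioms) for (x in tb$classes)
      if (class_sat(x, ax$rhs)) s_add(subs, c(x, ax$lhs))
    if (s_size(subs) + s_size(cex) == n0) break
  }

  types <- new_set(); roles <- new_set()
  for (r in seq_len(nrow(ab$types)))
    s_add(types, c(ab$types$individual[r], ab$types$class[r]))
  for (r in seq_len(nrow(ab$roles)))
    s_add(roles, c(ab$roles$property[r], ab$roles$subject[r],
                   ab$roles$object[r]))
  named_disj <- function(e) {
    if (e$variant == "named") return(e$term)
    if (e$variant == "or") {
      parts <- lapply(e$children, named_disj)
      if (any(vapply(parts, is.null, TRUE))) return(NULL)
      return(unlist(parts))
    }
    NULL
  }
  holds_n <- function(i, e) {
    switch(e$variant,
      named = s_has(types, c(i, e$term)),
      and = all(vapply(e$children, function(ch) holds_n(i, ch), TRUE)),
      or = any(vapply(e$children, function(ch) holds_n(i, ch), TRUE)),
      some = {
        direct <- any(vapply(roles$items, function(f)
          f[1] == e$property && f[2] == i && holds_n(f[3], e$filler), TRUE))
        if (direct) return(TRUE)
        nd <- named_disj(e$filler)
        if (is.null(nd)) return(FALSE)
        any(vapply(cex$items, function(f) {
          f[2] == e$property && s_has(types, c(i, f[1])) &&
            any(vapply(nd, function(nm) sub_in(f[3], nm), TRUE))
        }, TRUE))
      }
    )
  }
  inds <- ab$individuals
  repeat {
    n0 <- s_size(types) + s_size(roles)
    for (f in roles$items) for (q in psup[[f[1]]])
      s_add(roles, c(q, f[2], f[3]))
    for (f in roles$items)
      if (!is.null(inv[[f[1]]]))
        s_add(roles, c(inv[[f[1]]], f[3], f[2]))
    for (p in trans) for (f in roles$items) for (g in roles$items)
      if (f[1] == p && g[1] == p && f[3] == g[2])
        s_add(roles, c(p, f[2], g[3]))
    for (ch in tb$chain_axioms) for (f in roles$items) for (g in roles$items)
      if (f[1] == ch[1] && g[1] == ch[2] && f[3] == g[2] && f[2] != g[3])
        s_add(roles, c(ch[3], f[2], g[3]))
    for (f in types$items) for (b in subs$items)
      if (f[2] == b[1]) s_add(types, c(f[1], b[2]))
    for (ax in tb$equivalence_axioms) for (i in inds)
      if (holds_n(i, ax$rhs)) s_add(types, c(i, ax$lhs))
    if (s_size(types) + s_size(roles) == n0) break
  }
  list(subs = sort(subs$keys), cex = sort(cex$keys),
       types = sort(types$keys), roles = sort(roles$keys),
       holds = holds_n)
}

saturated_keys <- function(s) {
  list(subs = sort(paste(s$subsumptions$sub, s$subsumptions$super, sep = "|")),
       cex = sort(paste(s$class_existentials$class, s$class_existentials$property,
                        s$class_existentials$filler, sep = "|")),
       types = sort(paste(s$types$individual, s$types$class, sep = "|")),
       roles = sort(paste(s$roles$property, s$roles$subject, s$roles$object,
                          sep = "|")))
}

# ---- random knowledge bases ----

random_kb <- function(seed) {
  set.seed(seed)
  ncl <- sample(3:8, 1)
  classes <- paste0("hco:C", seq_len(ncl))
  np <- sample(2:4, 1)
  pn <- paste0("hco:p", seq_len(np))
  props <- list()
  inv_partner <- rep(NA_character_, np)
  if (np >= 2 && stats::runif(1) < 0.6) {
    inv_partner[1] <- pn[2]; inv_partner[2] <- pn[1]
  }
  for (i in seq_len(np)) {
    sym <- is.na(inv_partner[i]) && stats::runif(1) < 0.25
    sup <- if (i > 1 && stats::runif(1) < 0.4) sample(pn[seq_len(i - 1)], 1) else character()
    props[[i]] <- property_decl(pn[i],
                                inverse = if (!is.na(inv_partner[i])) inv_partner[i],
                                transitive = stats::runif(1) < 0.3,
                                symmetric = sym,
                                super_properties = sup)
  }
  rand_expr <- function(depth = 2) {
    pickc <- function() ce_named(sample(classes, 1))
    if (depth == 0 || stats::runif(1) < 0.4) return(pickc())
    switch(sample(3, 1),
           ce_some(sample(pn, 1), rand_expr(depth - 1)),
           ce_and(pickc(), rand_expr(depth - 1)),
           ce_or(pickc(), pickc()))
  }
  sub_ax <- lapply(seq_len(sample(1:4, 1)), function(i)
    list(lhs = sample(classes, 1),
         rhs = if (stats::runif(1) < 0.5) ce_named(sample(classes, 1))
               else ce_some(sample(pn, 1), ce_named(sample(classes, 1)))))
  eq_ax <- lapply(seq_len(sample(0:2, 1)), function(i)
    list(lhs = sample(classes, 1),
         rhs = ce_and(ce_named(sample(classes, 1)), rand_expr(1))))
  chains <- if (stats::runif(1) < 0.5)
    list(c(sample(pn, 1), sample(pn, 1), sample(pn, 1))) else list()
  ni <- sample(2:12, 1)
  inds <- paste0("hco:i", seq_len(ni))
  nt <- sample(1:8, 1)
  types <- data.frame(individual = sample(inds, nt, replace = TRUE),
                      class = sample(classes, nt, replace = TRUE),
                      stringsAsFactors = FALSE)
  nr <- sample(2:14, 1)
  roles <- data.frame(property = sample(pn, nr, replace = TRUE),
                      subject = sample(inds, nr, replace = TRUE),
                      object = sample(inds, nr, replace = TRUE),
                      stringsAsFactors = FALSE)
  kb(tbox(classes = classes, properties = props, subclass_axioms = sub_ax,
          equivalence_axioms = eq_ax, chain_axioms = chains),
     abox(individuals = inds, types = types, roles = roles))
}
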