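#' Rule-based materialization (saturation) engine
#'
#' Replaces a tableau reasoner for the fragment the connectomics schema
#' actually uses: named subsumption, defined classes built from
#' conjunction/disjunction of existential restrictions, a role hierarchy
#' with inverses, symmetry and transitivity, and a single role chain
#' (\code{is_tracto_connected o tracto_connects -> mr_connection}).
#' [saturate()] computes the least fixpoint of the rule set; queries are
#' evaluated against the saturated store only.
#'
#' The engine is sound but deliberately incomplete relative to full OWL DL:
#' disjunction is handled definitionally (no tableau branching), there is no
#' negation or cardinality, and the open-world reading means absence of a
#' fact never derives anything. Every knowledge base in this fragment is
#' satisfiable, so consistency checking reduces to the integrity checks.
#'
#' The chain rule never derives a reflexive connection: a node trivially
#' reaches itself through its own route, but an MR connection links two
#' different nodes, so conclusions with identical endpoints are suppressed.
#'
#' @name reasoner
NULL

.k_rows <- function(df) do.call(paste, c(unname(as.list(df)), sep = "\r"))

.store <- function(df) list(df = df, keys = .k_rows(df))

# add rows to a store, deduplicating; optionally record trace entries
.grow <- function(store, new, rule = NULL, premises = NULL, tracer = NULL,
                  fact = NULL) {
  if (nrow(new) == 0) return(store)
  keys <- .k_rows(new)
  fresh <- !(keys %in% store$keys) & !duplicated(keys)
  if (!any(fresh)) return(store)
  if (!is.null(tracer) && !is.null(rule)) {
    concl <- paste0(fact, "(", gsub("\r", ", ", keys[fresh]), ")")
    if (!is.null(premises) && length(premises) == 1)
      premises <- rep(premises, nrow(new))
    prem <- if (is.null(premises)) "" else premises[fresh]
    tracer$entries[[length(tracer$entries) + 1L]] <-
      data.frame(rule = rule, premises = prem, conclusion = concl,
                 stringsAsFactors = FALSE)
  }
  store$df <- rbind(store$df, new[fresh, , drop = FALSE])
  store$keys <- c(store$keys, keys[fresh])
  store
}

# generic two-frame join producing a data.frame with named columns
.join <- function(a, b, out_names) {
  j <- merge(a, b, by = "y")
  res <- j[, c("x", "z"), drop = FALSE]
  names(res) <- out_names
  res
}

# reflexive-transitive closure of the super-property graph
.property_closure <- function(properties) {
  pnames <- names(properties)
  pairs <- data.frame(sub = pnames, super = pnames, stringsAsFactors = FALSE)
  for (p in properties) {
    if (length(p$super_properties) > 0)
      pairs <- rbind(pairs, data.frame(sub = p$name, super = p$super_properties,
                                       stringsAsFactors = FALSE))
  }
  pairs <- unique(pairs)
  repeat {
    a <- pairs; names(a) <- c("x", "y")
    b <- pairs; names(b) <- c("y", "z")
    new <- unique(.join(a, b, c("sub", "super")))
    merged <- unique(rbind(pairs, new))
    if (nrow(merged) == nrow(pairs)) break
    pairs <- merged
  }
  pairs
}

# decompose an axiom lhs <= rhs into named subsumptions and class-level
# existentials (named fillers only -- the fragment's axioms have no others)
.decompose_axiom <- function(lhs, rhs) {
  subs <- list(); cex <- list()
  rec <- function(expr) {
    switch(expr$variant,
      named = subs[[length(subs) + 1L]] <<- c(lhs, expr$term),
      some  = if (expr$filler$variant == "named")
        cex[[length(cex) + 1L]] <<- c(lhs, expr$property, expr$filler$term),
      and   = for (ch in expr$children) rec(ch),
      or    = invisible(NULL)  # disjunctive RHS carries no definite consequence
    )
  }
  rec(rhs)
  list(subs = subs, cex = cex)
}

# classes X with X subsumed-by expr, given current subsumption/existential
# stores (used by rule T4 and for anonymous-filler query entailment)
.sat_classes <- function(expr, subs_df, cex_df) {
  switch(expr$variant,
    named = subs_df$sub[subs_df$super == expr$term],
    and = Reduce(intersect, lapply(expr$children, .sat_classes,
                                   subs_df = subs_df, cex_df = cex_df)),
    or = unique(unlist(lapply(expr$children, .sat_classes,
                              subs_df = subs_df, cex_df = cex_df))),
    some = {
      fillers <- .sat_classes(expr$filler, subs_df, cex_df)
      unique(cex_df$class[cex_df$property == expr$property &
                            cex_df$filler %in% fillers])
    }
  )
}

# if expr is a named class or a disjunction of named classes, return the
# named terms; otherwise NULL (anonymous-filler entailment applies only then)
.named_disjuncts <- function(expr) {
  if (expr$variant == "named") return(expr$term)
  if (expr$variant == "or") {
    terms <- lapply(expr$children, .named_disjuncts)
    if (any(vapply(terms, is.null, TRUE))) return(NULL)
    return(unique(unlist(terms)))
  }
  NULL
}

# individuals satisfying expr over the derived stores
.eval_expr_set <- function(expr, st) {
  switch(expr$variant,
    named = st$types$df$individual[st$types$df$class == expr$term],
    and = Reduce(intersect, lapply(expr$children, .eval_expr_set, st = st)),
    or = unique(unlist(lapply(expr$children, .eval_expr_set, st = st))),
    some = {
      p <- expr$property
      rl <- st$roles$df
      inside <- .eval_expr_set(expr$filler, st)
      hit <- unique(rl$subject[rl$property == p & rl$object %in% inside])
      # anonymous-filler entailment via class-level existentials
      nd <- .named_disjuncts(expr$filler)
      if (!is.null(nd)) {
        ok_fillers <- unique(st$subs$df$sub[st$subs$df$super %in% nd])
        cexp <- st$cex$df[st$cex$df$property == p &
                            st$cex$df$filler %in% ok_fillers, , drop = FALSE]
        if (nrow(cexp) > 0) {
          ty <- st$types$df
          hit <- unique(c(hit, ty$individual[ty$class %in% cexp$class]))
        }
      }
      hit
    }
  )
}

#' Saturate a knowledge base
#'
#' Computes the least fixpoint of the materialization rules. TBox level:
#' reflexivity, both directions of equivalence definitions, subsumption
#' transitivity, definitional conjunction/disjunction introduction,
#' propagation of class-level existentials along the role hierarchy,
#' transitive roles and filler subsumption. ABox level: type inheritance,
#' role-hierarchy propagation, inverses, symmetry, transitivity, the role
#' chain (distinct endpoints only) and realization of defined classes.
#' Termination is guaranteed by the finite fact space and the result is
#' independent of rule application order (the trace is not).
#'
#' @param x an \code{hco_kb}.
#' @param trace record a derivation trace (rule id, premises, conclusion)
#'   for every derived fact; slower, default FALSE.
#' @return an object of class \code{hco_saturated_kb} with elements
#'   \code{kb}, \code{subsumptions}, \code{class_existentials},
#'   \code{types}, \code{roles}, \code{property_closure} and (if requested)
#'   \code{trace}.
#' @examples
#' s <- saturate(kb(build_hco_schema()))
#' nrow(s$subsumptions)
#' @export
saturate <- function(x, trace = FALSE) {
  validate_kb(x)
  tb <- x$tbox; ab <- x$abox
  tracer <- if (trace) new.env() else NULL
  if (trace) tracer$entries <- list()

  prop_closure <- .property_closure(tb$properties)
  inverses <- vapply(tb$properties, function(p)
    if (is.null(p$inverse)) NA_character_ else p$inverse, "")
  transitive_props <- names(tb$properties)[vapply(tb$properties, `[[`, TRUE, "transitive")]

  # ---- TBox saturation ----
  subs <- .store(data.frame(sub = tb$classes, super = tb$classes,
                            stringsAsFactors = FALSE))
  cex <- .store(data.frame(class = character(), property = character(),
                           filler = character(), stringsAsFactors = FALSE))
  seed_axioms <- c(tb$subclass_axioms, tb$equivalence_axioms)
  for (ax in seed_axioms) {
    d <- .decompose_axiom(ax$lhs, ax$rhs)
    if (length(d$subs) > 0) {
      m <- do.call(rbind, d$subs)
      subs <- .grow(subs, data.frame(sub = m[, 1], super = m[, 2],
                                     stringsAsFactors = FALSE),
                    rule = "asserted", tracer = tracer, fact = "sub")
    }
    if (length(d$cex) > 0) {
      m <- do.call(rbind, d$cex)
      cex <- .grow(cex, data.frame(class = m[, 1], property = m[, 2],
                                   filler = m[, 3], stringsAsFactors = FALSE),
                   rule = "asserted", tracer = tracer, fact = "cex")
    }
  }

  repeat {
    n0 <- length(subs$keys) + length(cex$keys)
    # T3 transitivity of subsumption
    a <- subs$df; names(a) <- c("x", "y")
    b <- subs$df; names(b) <- c("y", "z")
    t3 <- .join(a, b, c("sub", "super"))
    subs <- .grow(subs, t3, rule = "T3",
                  premises = paste0("sub(", t3$sub, ", _), sub(_, ", t3$super, ")"),
                  tracer = tracer, fact = "sub")
    # T5 existential propagation along the role hierarchy
    strict <- prop_closure[prop_closure$sub != prop_closure$super, , drop = FALSE]
    if (nrow(strict) > 0 && nrow(cex$df) > 0) {
      j <- merge(cex$df, strict, by.x = "property", by.y = "sub")
      t5 <- data.frame(class = j$class, property = j$super, filler = j$filler,
                       stringsAsFactors = FALSE)
      cex <- .grow(cex, t5, rule = "T5",
                   premises = paste0("cex(", t5$class, ", sub-of-", t5$property,
                                     ", ", t5$filler, ")"),
                   tracer = tracer, fact = "cex")
    }
    # T6 transitive roles at class level
    for (p in transitive_props) {
      e <- cex$df[cex$df$property == p, , drop = FALSE]
      if (nrow(e) == 0) next
      a <- e[, c("class", "filler")]; names(a) <- c("x", "y")
      b <- e[, c("class", "filler")]; names(b) <- c("y", "z")
      t6 <- .join(a, b, c("class", "filler"))
      if (nrow(t6) == 0) next
      t6 <- data.frame(class = t6$class, property = p, filler = t6$filler,
                       stringsAsFactors = FALSE)
      cex <- .grow(cex, t6, rule = "T6",
                   premises = paste0("cex chain over transitive ", p),
                   tracer = tracer, fact = "cex")
    }
    # T7 filler subsumption
    if (nrow(cex$df) > 0) {
      j <- merge(cex$df, subs$df, by.x = "filler", by.y = "sub")
      t7 <- data.frame(class = j$class, property = j$property, filler = j$super,
                       stringsAsFactors = FALSE)
      cex <- .grow(cex, t7, rule = "T7",
                   premises = paste0("cex(", t7$class, ", ", t7$property,
                                     ", sub-of-", t7$filler, ")"),
                   tracer = tracer, fact = "cex")
    }
    # T4 definitional introduction
    for (ax in tb$equivalence_axioms) {
      xs <- .sat_classes(ax$rhs, subs$df, cex$df)
      if (length(xs) == 0) next
      t4 <- data.frame(sub = xs, super = ax$lhs, stringsAsFactors = FALSE)
      subs <- .grow(subs, t4, rule = "T4",
                    premises = paste0(t4$sub, " below definition of ", ax$lhs),
                    tracer = tracer, fact = "sub")
    }
    if (length(subs$keys) + length(cex$keys) == n0) break
  }

  # ---- ABox saturation ----
  types <- .store(ab$types)
  roles <- .store(ab$roles)
  st <- list(types = types, roles = roles, subs = subs, cex = cex)
  repeat {
    n0 <- length(types$keys) + length(roles$keys)
    rl <- roles$df
    # A2 role hierarchy
    strict <- prop_closure[prop_closure$sub != prop_closure$super, , drop = FALSE]
    if (nrow(strict) > 0 && nrow(rl) > 0) {
      j <- merge(rl, strict, by.x = "property", by.y = "sub")
      a2 <- data.frame(property = j$super, subject = j$subject, object = j$object,
                       stringsAsFactors = FALSE)
      roles <- .grow(roles, a2, rule = "A2",
                     premises = paste0("sub-property assertion for ", a2$property),
                     tracer = tracer, fact = "role")
    }
    # A3/A4 inverses (a symmetric property is its own inverse)
    rl <- roles$df
    has_inv <- rl$property %in% names(inverses)[!is.na(inverses)]
    if (any(has_inv)) {
      r <- rl[has_inv, , drop = FALSE]
      a3 <- data.frame(property = unname(inverses[r$property]),
                       subject = r$object, object = r$subject,
                       stringsAsFactors = FALSE)
      roles <- .grow(roles, a3, rule = "A3",
                     premises = paste0("inverse of ", r$property, "(",
                                       r$subject, ", ", r$object, ")"),
                     tracer = tracer, fact = "role")
    }
    # A5 transitive roles
    for (p in transitive_props) {
      r <- roles$df[roles$df$property == p, c("subject", "object"), drop = FALSE]
      if (nrow(r) == 0) next
      a <- r; names(a) <- c("x", "y")
      b <- r; names(b) <- c("y", "z")
      a5 <- .join(a, b, c("subject", "object"))
      if (nrow(a5) == 0) next
      a5 <- data.frame(property = p, subject = a5$subject, object = a5$object,
                       stringsAsFactors = FALSE)
      roles <- .grow(roles, a5, rule = "A5",
                     premises = paste0("transitive ", p),
                     tracer = tracer, fact = "role")
    }
    # A6 role chain, distinct endpoints only
    for (ch in tb$chain_axioms) {
      r1 <- roles$df[roles$df$property == ch[1], c("subject", "object"), drop = FALSE]
      r2 <- roles$df[roles$df$property == ch[2], c("subject", "object"), drop = FALSE]
      if (nrow(r1) == 0 || nrow(r2) == 0) next
      names(r1) <- c("x", "y"); names(r2) <- c("y", "z")
      a6 <- .join(r1, r2, c("subject", "object"))
      a6 <- a6[a6$subject != a6$object, , drop = FALSE]
      if (nrow(a6) == 0) next
      a6 <- data.frame(property = ch[3], subject = a6$subject, object = a6$object,
                       stringsAsFactors = FALSE)
      roles <- .grow(roles, a6, rule = "A6",
                     premises = paste0(ch[1], " o ", ch[2]),
                     tracer = tracer, fact = "role")
    }
    # A1 type inheritance
    ty <- types$df
    if (nrow(ty) > 0) {
      j <- merge(ty, subs$df, by.x = "class", by.y = "sub")
      a1 <- data.frame(individual = j$individual, class = j$super,
                       stringsAsFactors = FALSE)
      types <- .grow(types, a1, rule = "A1",
                     premises = paste0("inherited into ", a1$class),
                     tracer = tracer, fact = "type")
    }
    # A7 realization of defined classes
    st$types <- types; st$roles <- roles
    for (ax in tb$equivalence_axioms) {
      inds <- .eval_expr_set(ax$rhs, st)
      if (length(inds) == 0) next
      a7 <- data.frame(individual = inds, class = ax$lhs, stringsAsFactors = FALSE)
      types <- .grow(types, a7, rule = "A7",
                     premises = paste0("satisfies definition of ", ax$lhs),
                     tracer = tracer, fact = "type")
      st$types <- types
    }
    if (length(types$keys) + length(roles$keys) == n0) break
  }

  out <- structure(list(
    kb = x,
    subsumptions = {
      d <- subs$df[order(subs$df$sub, subs$df$super), , drop = FALSE]
      rownames(d) <- NULL; d
    },
    class_existentials = {
      d <- cex$df[order(cex$df$class, cex$df$property, cex$df$filler), , drop = FALSE]
      rownames(d) <- NULL; d
    },
    types = {
      d <- types$df[order(types$df$individual, types$df$class), , drop = FALSE]
      rownames(d) <- NULL; d
    },
    roles = {
      d <- roles$df[order(roles$df$property, roles$df$subject, roles$df$object), ,
                    drop = FALSE]
      rownames(d) <- NULL; d
    },
    property_closure = prop_closure
  ), class = "hco_saturated_kb")
  if (trace) {
    out$trace <- if (length(tracer$entries) > 0)
      do.call(rbind, tracer$entries)
    else data.frame(rule = character(), premises = character(),
                    conclusion = character(), stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.hco_saturated_kb <- function(x, ...) {
  cat("<saturated KB> ", nrow(x$subsumptions), " subsumptions, ",
      nrow(x$class_existentials), " class existentials, ",
      nrow(x$types), " type facts, ", nrow(x$roles), " role facts\n", sep = "")
  invisible(x)
}

.check_expr_vocab <- function(expr, tb) {
  miss_c <- setdiff(ce_class_terms(expr), tb$classes)
  if (length(miss_c) > 0)
    stop("unknown class term(s) in expression: ", paste(miss_c, collapse = ", "))
  miss_p <- setdiff(ce_property_terms(expr), names(tb$properties))
  if (length(miss_p) > 0)
    stop("unknown property term(s) in expression: ", paste(miss_p, collapse = ", "))
  invisible(TRUE)
}

#' Does an individual satisfy a class expression?
#'
#' Membership check against a saturated knowledge base: a named class holds
#' when the type fact is derived; conjunction/disjunction recurse; an
#' existential holds either through a derived role edge into the filler set
#' or -- when the filler reduces to a named class or a disjunction of named
#' classes -- through a class-level existential on one of the individual's
#' types (anonymous-filler entailment).
#'
#' @param individual individual term name.
#' @param expr a class expression.
#' @param s an \code{hco_saturated_kb}.
#' @return logical scalar.
#' @export
holds <- function(individual, expr, s) {
  stopifnot(inherits(s, "hco_saturated_kb"), inherits(expr, "hco_expr"))
  .check_expr_vocab(expr, s$kb$tbox)
  st <- list(types = list(df = s$types), roles = list(df = s$roles),
             subs = list(df = s$subsumptions),
             cex = list(df = s$class_existentials))
  individual %in% .eval_expr_set(expr, st)
}
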