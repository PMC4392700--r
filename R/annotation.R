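#' Labeled connectivity matrices
#'
#' A region matrix holds non-negative connectivity values between the target
#' regions of a tractography run: rows are the parcels of the first target
#' mask, columns the remaining parcels and regions. One matrix exists per
#' white-matter seed mask; when the seed mask is an anatomically labeled
#' fiber bundle the matrix carries the bundle class as \code{seed_label}
#' (rest-of-white-matter seeds have none). A binary matrix is the same
#' container after thresholding, with values restricted to \{0, 1\}.
#'
#' @param values numeric matrix with unique row and column dimnames.
#' @param seed_label optional fiber-bundle class term.
#' @return an object of class \code{hco_region_matrix} (additionally
#'   \code{hco_binary_matrix} for [binary_matrix()]).
#' @export
region_matrix <- function(values, seed_label = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("row and column labels are required")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("row/column labels must be unique")
  if (any(values < 0)) stop("connectivity values must be non-negative")
  structure(list(seed_label = if (!is.null(seed_label)) as_term(seed_label),
                 values = values),
            class = "hco_region_matrix")
}

#' @rdname region_matrix
#' @export
binary_matrix <- function(values, seed_label = NULL) {
  m <- region_matrix(values, seed_label)
  if (!all(m$values %in% c(0, 1))) stop("binary matrix must contain only 0/1")
  class(m) <- c("hco_binary_matrix", class(m))
  m
}

#' @export
print.hco_region_matrix <- function(x, ...) {
  cat("<", if (inherits(x, "hco_binary_matrix")) "binary" else "region",
      " matrix> ", nrow(x$values), " x ", ncol(x$values), ", seed: ",
      if (is.null(x$seed_label)) "(rest of white matter)" else x$seed_label,
      "\n", sep = "")
  invisible(x)
}

#' Aggregate a voxel-wise matrix to region level
#'
#' The region-to-region connectivity is the arithmetic mean of the voxel-wise
#' values over all voxel pairs belonging to the two regions.
#'
#' @param voxel_matrix non-negative numeric matrix with voxel labels as
#'   dimnames.
#' @param voxel_to_region named character vector mapping every voxel label
#'   (rows and columns) to its region identifier.
#' @return a numeric matrix with region labels, rows/columns sorted.
#' @export
aggregate_voxelwise <- function(voxel_matrix, voxel_to_region) {
  if (!is.matrix(voxel_matrix) || !is.numeric(voxel_matrix))
    stop("voxel_matrix must be a numeric matrix")
  if (any(voxel_matrix < 0)) stop("connectivity values must be non-negative")
  labs <- c(rownames(voxel_matrix), colnames(voxel_matrix))
  if (is.null(labs)) stop("voxel labels are required")
  miss <- setdiff(labs, names(voxel_to_region))
  if (length(miss) > 0)
    stop("unmapped voxel label(s): ", paste(utils::head(miss, 5), collapse = ", "))
  rg <- voxel_to_region[rownames(voxel_matrix)]
  cg <- voxel_to_region[colnames(voxel_matrix)]
  if (any(!nzchar(rg)) || any(!nzchar(cg))) stop("empty region identifier")
  sums <- rowsum(voxel_matrix, group = rg)
  sums <- t(rowsum(t(sums), group = cg))
  counts <- outer(as.vector(table(rg)[rownames(sums)]),
                  as.vector(table(cg)[colnames(sums)]))
  sums / counts
}

#' Annotation configuration
#'
#' Post-processing and naming conventions for turning region matrices into
#' semantic annotations. The default post-processing is natural \code{log1p}
#' (handles zero connectivity without a pseudo-count), division of each row
#' by its maximum (so the threshold reads "at least 70 percent of the
#' strongest log-connectivity in the row", and every non-empty row keeps at
#' least one connection), and thresholding at 0.7 with ties kept.
#'
#' @param threshold binarization threshold in (0, 1]; default 0.7, the value
#'   used to keep only connections reconstructed with high probability.
#' @param log_transform currently \code{"log1p_natural"}.
#' @param row_normalization currently \code{"divide_by_row_max"}.
#' @param node_name_template,route_name_template naming templates with
#'   \code{\{subject\}}, \code{\{region\}}, \code{\{parcel_id\}},
#'   \code{\{counter\}} slots; instances live in the \code{hco} namespace.
#' @return a list of class \code{hco_annotation_config}.
#' @export
annotation_config <- function(threshold = 0.7,
                              log_transform = "log1p_natural",
                              row_normalization = "divide_by_row_max",
                              node_name_template = "{subject}_gray_matter_of_{region}_{parcel_id}",
                              route_name_template = "{subject}_mr_route_{counter}") {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  log_transform <- match.arg(log_transform, "log1p_natural")
  row_normalization <- match.arg(row_normalization, "divide_by_row_max")
  structure(list(threshold = threshold, log_transform = log_transform,
                 row_normalization = row_normalization,
                 node_name_template = node_name_template,
                 route_name_template = route_name_template),
            class = "hco_annotation_config")
}

#' Binarize a region matrix
#'
#' Applies the configured log transform element-wise, divides each row by its
#' row maximum (all-zero rows stay all-zero), and keeps entries whose
#' normalized value reaches the threshold. The comparison is \code{>=}, so
#' the row maximum always survives and exact ties with the threshold are
#' kept. Note the procedure is scale-detecting, not scale-invariant:
#' rescaling a row changes log-ratios, which is intended -- the log is part
#' of the connectivity model, not a display transform.
#'
#' @param m an [region_matrix()] (or plain labeled matrix).
#' @param config an [annotation_config()].
#' @return an [binary_matrix()] with the same labels and seed label.
#' @examples
#' m <- region_matrix(matrix(c(9, 99, 0), 1, 3,
#'                    dimnames = list("r1", c("a", "b", "c"))))
#' binarize_matrix(m)$values  # 0 1 0 at the default 0.7 threshold
#' @export
binarize_matrix <- function(m, config = annotation_config()) {
  if (!inherits(m, "hco_region_matrix")) m <- region_matrix(m)
  v <- m$values
  if (any(v < 0)) stop("connectivity values must be non-negative")
  y <- log1p(v)
  rmax <- apply(y, 1, max)
  norm <- y / ifelse(rmax > 0, rmax, 1)   # all-zero rows stay all-zero
  b <- (norm >= config$threshold) * 1
  dimnames(b) <- dimnames(v)
  binary_matrix(b, m$seed_label)
}

#' Parcellation and adjacency containers
#'
#' A parcellation lists, for one subject, the high-resolution cortical
#' parcels with the gyrus-level region class each parcel overlaps, the
#' non-cortical extra regions (thalamus, basal ganglia, brainstem, ...), and
#' per-region partonomy hints: the chain of part-of steps from the region to
#' its enclosing lobe, segment and hemisphere, used to build each region
#' individual's part-whole context.
#'
#' @param subject_id subject identifier, e.g. \code{"s1"}.
#' @param parcels data.frame with columns \code{parcel_id} (integer, unique),
#'   \code{region_term}, \code{hemisphere} (\code{left}/\code{right}/
#'   \code{midline}).
#' @param extra_regions data.frame with columns \code{region_id},
#'   \code{region_term}.
#' @param partonomy_hints named list: region term -> data.frame with columns
#'   \code{property}, \code{ancestor} (ordered chain steps).
#' @return an object of class \code{hco_parcellation}.
#' @export
parcellation <- function(subject_id, parcels,
                         extra_regions = data.frame(region_id = character(),
                                                    region_term = character()),
                         partonomy_hints = list()) {
  if (anyDuplicated(parcels$parcel_id))
    stop("duplicate parcel ids in parcellation of ", subject_id)
  structure(list(subject_id = subject_id,
                 parcels = data.frame(parcel_id = as.integer(parcels$parcel_id),
                                      region_term = as_term(as.character(parcels$region_term)),
                                      hemisphere = as.character(parcels$hemisphere),
                                      stringsAsFactors = FALSE),
                 extra_regions = data.frame(region_id = as.character(extra_regions$region_id),
                                            region_term = as_term(as.character(extra_regions$region_term)),
                                            stringsAsFactors = FALSE),
                 partonomy_hints = partonomy_hints),
            class = "hco_parcellation")
}

#' @rdname parcellation
#' @param edges data.frame with columns \code{a}, \code{b}: unordered pairs
#'   of parcel ids / region ids that are nearest neighbors. Self-pairs are
#'   rejected.
#' @export
adjacency <- function(edges = data.frame(a = character(), b = character())) {
  edges <- data.frame(a = as.character(edges$a), b = as.character(edges$b),
                      stringsAsFactors = FALSE)
  if (any(edges$a == edges$b)) stop("adjacency contains a self-pair")
  key <- ifelse(edges$a < edges$b, paste(edges$a, edges$b), paste(edges$b, edges$a))
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "hco_adjacency")
}

.fill_template <- function(template, subject = "", region = "", parcel_id = "",
                           counter = "") {
  out <- gsub("{subject}", subject, template, fixed = TRUE)
  out <- gsub("{region}", region, out, fixed = TRUE)
  out <- gsub("{parcel_id}", parcel_id, out, fixed = TRUE)
  gsub("{counter}", counter, out, fixed = TRUE)
}

#' Annotate one subject's connectivity data
#'
#' Populates an ABox from a parcellation, a nearest-neighbor adjacency and
#' the per-seed binary connectivity matrices. Every parcel becomes a
#' gray-matter-part individual linked by \code{fma:regional_part_of} to a
#' per-subject gray-matter-of-region individual, which is
#' \code{fma:constitutional_part_of} the per-subject region individual typed
#' with its region class; the region individual carries the partonomy-hint
#' chain up to lobe and hemisphere. Each adjacency edge yields one
#' \code{hco:continuous_with} assertion (one direction; symmetry is derived
#' by the reasoner). Each 1-cell yields an \code{hco:mr_connection} between
#' the two endpoints and one fresh \code{hco:MR_Route} individual with
#' \code{hco:tracto_connects} to both; routes of a seed-labeled matrix are
#' \code{fma:regional_part_of} the per-subject bundle individual, created on
#' first use. Route numbering is fixed: matrices in input order, cells in
#' row-major order, so instance names are reproducible across runs.
#'
#' @param parc an [parcellation()].
#' @param adj an [adjacency()].
#' @param matrices list of [binary_matrix()] objects.
#' @param tbox the TBox all region terms must resolve against.
#' @param config an [annotation_config()].
#' @return an \code{hco_abox}.
#' @export
annotate_subject <- function(parc, adj, matrices, tbox,
                             config = annotation_config()) {
  stopifnot(inherits(parc, "hco_parcellation"), inherits(adj, "hco_adjacency"))
  subj <- parc$subject_id
  region_terms <- unique(c(parc$parcels$region_term, parc$extra_regions$region_term))
  miss <- setdiff(region_terms, tbox$classes)
  if (length(miss) > 0)
    stop("region term(s) not in TBox: ", paste(utils::head(miss, 5), collapse = ", "))

  individuals <- character()
  types <- list(); roles <- list()
  created <- new.env(parent = emptyenv())
  add_type <- function(i, cl) types[[length(types) + 1L]] <<-
    data.frame(individual = i, class = cl, stringsAsFactors = FALSE)
  add_role <- function(p, s, o) roles[[length(roles) + 1L]] <<-
    data.frame(property = p, subject = s, object = o, stringsAsFactors = FALSE)
  add_ind <- function(i) individuals <<- c(individuals, i)

  # per-subject anatomical individual for a region class, with its
  # partonomy-hint chain; created lazily, shared within the subject
  region_individual <- function(term, name = NULL) {
    if (is.null(name))
      name <- paste0("hco:", subj, "_", tolower(term_local(term)))
    if (!is.null(created[[name]])) return(name)
    created[[name]] <- TRUE
    add_ind(name); add_type(name, term)
    hints <- parc$partonomy_hints[[term]]
    if (!is.null(hints) && nrow(hints) > 0) {
      cur <- name
      for (i in seq_len(nrow(hints))) {
        anc_term <- as_term(hints$ancestor[i])
        anc_name <- paste0("hco:", subj, "_", tolower(term_local(anc_term)))
        if (is.null(created[[anc_name]])) {
          created[[anc_name]] <- TRUE
          add_ind(anc_name); add_type(anc_name, anc_term)
        }
        add_role(as_term(hints$property[i]), cur, anc_name)
        cur <- anc_name
      }
    }
    name
  }

  # parcels: parcel -> gray-matter-of-region -> region individual chain
  id_to_ind <- character()
  for (i in seq_len(nrow(parc$parcels))) {
    p <- parc$parcels[i, ]
    region_lower <- tolower(term_local(p$region_term))
    node <- paste0("hco:", .fill_template(config$node_name_template,
                                          subject = subj, region = region_lower,
                                          parcel_id = p$parcel_id))
    gm <- paste0("hco:", subj, "_gray_matter_of_", region_lower)
    region_ind <- region_individual(p$region_term)
    if (is.null(created[[gm]])) {
      created[[gm]] <- TRUE
      add_ind(gm); add_type(gm, "hco:Gray_matter_part")
      add_role("fma:constitutional_part_of", gm, region_ind)
    }
    add_ind(node); add_type(node, "hco:Gray_matter_part")
    add_role("fma:regional_part_of", node, gm)
    id_to_ind[as.character(p$parcel_id)] <- node
  }
  # extra (non-cortical) regions are nodes in their own right
  for (i in seq_len(nrow(parc$extra_regions))) {
    r <- parc$extra_regions[i, ]
    name <- region_individual(r$region_term, name = paste0("hco:", subj, "_", r$region_id))
    add_type(name, "hco:Gray_matter_part")
    id_to_ind[r$region_id] <- name
  }

  # nearest-neighbor topology
  for (i in seq_len(nrow(adj$edges))) {
    e <- adj$edges[i, ]
    a <- id_to_ind[e$a]; b <- id_to_ind[e$b]
    if (is.na(a) || is.na(b))
      stop("adjacency endpoint not in parcellation: ",
           if (is.na(a)) e$a else e$b)
    add_role("hco:continuous_with", a, b)
  }

  # connectivity: one route per 1-cell, numbered across matrices
  counter <- 0L
  for (m in matrices) {
    if (!inherits(m, "hco_binary_matrix"))
      stop("matrices must be binarized (see binarize_matrix)")
    labs <- c(rownames(m$values), colnames(m$values))
    miss <- setdiff(labs, names(id_to_ind))
    if (length(miss) > 0)
      stop("matrix label(s) not in parcellation: ",
           paste(utils::head(miss, 5), collapse = ", "))
    ones <- which(m$values == 1, arr.ind = TRUE)
    if (nrow(ones) == 0) next
    ones <- ones[order(ones[, "row"], ones[, "col"]), , drop = FALSE]  # row-major
    bundle <- if (!is.null(m$seed_label)) region_individual(m$seed_label)
    for (k in seq_len(nrow(ones))) {
      counter <- counter + 1L
      src <- id_to_ind[rownames(m$values)[ones[k, "row"]]]
      dst <- id_to_ind[colnames(m$values)[ones[k, "col"]]]
      if (src == dst)
        stop("self-connection in matrix for label ", src)
      route <- paste0("hco:", .fill_template(config$route_name_template,
                                             subject = subj, counter = counter))
      add_ind(route); add_type(route, "hco:MR_Route")
      add_role("hco:mr_connection", src, dst)
      add_role("hco:tracto_connects", route, src)
      add_role("hco:tracto_connects", route, dst)
      if (!is.null(bundle)) add_role("fma:regional_part_of", route, bundle)
    }
  }

  ab <- abox(individuals = individuals,
             types = do.call(rbind, types),
             roles = if (length(roles) > 0) do.call(rbind, roles) else
               data.frame(property = character(), subject = character(),
                          object = character()))
  validate_kb(kb(tbox, ab, validate = FALSE))
  ab
}
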