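# Minimum proton-proton distances within and between molecules from explicit
# Cartesian coordinates, for comparing dense-liquid NOE distances with
# crystal-packing contacts.

#' Construct a proton cloud from atom records
#'
#' A proton cloud is a flat table of proton positions grouped by molecule and
#' by proton group. The three groups relevant for the NOE comparison are the
#' alpha-methyl protons (`a`), the isopropyl methine/methylene protons (`b`)
#' and the isopropyl methyl protons (`c`); any label scheme is accepted.
#'
#' @param df data.frame with columns `x`, `y`, `z` (Angstrom), `mol_id`
#'   (molecule identifier) and `group` (proton-group label). An optional
#'   `element` column is kept if present.
#' @return Object of class `proton_cloud` (a validated data.frame).
#' @export
proton_cloud <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("x", "y", "z", "mol_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("proton cloud is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) < 1L) stop("proton cloud is empty")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)) || !all(is.finite(df$z)))
    stop("coordinates must be finite")
  df$mol_id <- as.character(df$mol_id)
  df$group <- as.character(df$group)
  structure(df, class = c("proton_cloud", "data.frame"))
}

#' Read an extended XYZ file of grouped proton coordinates
#'
#' Expects the XYZ layout `n_atoms / comment / atom lines`, with each atom
#' line carrying `element x y z mol_id group`. This pre-expanded cluster
#' format stands in for crystallographic symmetry expansion, which is outside
#' the scope of this package.
#'
#' @param path Path to the file.
#' @return A [proton_cloud()].
#' @export
read_xyz_groups <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not an extended XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("first line of ", path, " must be the atom count")
  body <- lines[seq(3, length.out = n)]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) < 6L)
  if (length(bad))
    stop("atom line(s) in ", path, " lack `element x y z mol_id group`: row ",
         bad[1])
  proton_cloud(data.frame(
    element = vapply(parts, `[[`, "", 1L),
    x = as.numeric(vapply(parts, `[[`, "", 2L)),
    y = as.numeric(vapply(parts, `[[`, "", 3L)),
    z = as.numeric(vapply(parts, `[[`, "", 4L)),
    mol_id = vapply(parts, `[[`, "", 5L),
    group = vapply(parts, `[[`, "", 6L)
  ))
}

#' Write a proton cloud as an extended XYZ file
#'
#' @param cloud A [proton_cloud()].
#' @param path Output path.
#' @param comment Comment line (second line of the file).
#' @export
write_xyz_groups <- function(cloud, path, comment = "proton cloud") {
  cloud <- proton_cloud(cloud)
  el <- if ("element" %in% names(cloud)) cloud$element else rep("H", nrow(cloud))
  lines <- c(nrow(cloud), comment,
             sprintf("%s %.6f %.6f %.6f %s %s",
                     el, cloud$x, cloud$y, cloud$z, cloud$mol_id, cloud$group))
  writeLines(lines, path)
  invisible(path)
}

#' Minimum intra- and intermolecular distances between two proton groups
#'
#' Exhaustively scans all proton pairs with the two requested group labels
#' and returns the minimum distance over same-molecule pairs (intramolecular)
#' and over different-molecule pairs (intermolecular). With a single molecule
#' in the cloud the intermolecular minimum is undefined and returned as `NA`
#' with `inter_defined = FALSE`.
#'
#' @param cloud A [proton_cloud()] or a data.frame accepted by it.
#' @param pair Character vector of two group labels, e.g. `c("a", "b")`.
#' @return List with `pair`, `intra_min_A`, `inter_min_A`, `inter_defined`.
#' @examples
#' cl <- proton_cloud(data.frame(x = c(0, 2), y = 0, z = 0,
#'                               mol_id = c("1", "2"), group = c("a", "b")))
#' min_group_distances(cl, c("a", "b"))
#' @export
min_group_distances <- function(cloud, pair) {
  cloud <- proton_cloud(cloud)
  stopifnot(is.character(pair), length(pair) == 2L)
  for (lab in unique(pair))
    if (!any(cloud$group == lab))
      stop("proton group label absent from cloud: ", lab)
  i1 <- which(cloud$group == pair[1])
  i2 <- which(cloud$group == pair[2])
  dx <- outer(cloud$x[i1], cloud$x[i2], "-")
  dy <- outer(cloud$y[i1], cloud$y[i2], "-")
  dz <- outer(cloud$z[i1], cloud$z[i2], "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  same_mol <- outer(cloud$mol_id[i1], cloud$mol_id[i2], "==")
  same_atom <- outer(i1, i2, "==")
  intra <- d[same_mol & !same_atom]
  inter <- d[!same_mol]
  list(pair = paste(pair, collapse = "-"),
       intra_min_A = if (length(intra)) min(intra) else NA_real_,
       inter_min_A = if (length(inter)) min(inter) else NA_real_,
       inter_defined = length(inter) > 0L)
}

#' Published crystal-contact distances for ibuprofen polymorph comparison
#'
#' Literature minimum proton-proton distances in the crystal structures of
#' racemic ibuprofen and of the pure S enantiomer, for the (a)-(b) and
#' (b)-(c) proton-group pairs. These are external reference constants taken
#' from published crystal structures (not computed by this package); they are
#' the yardstick against which dense-liquid NOE distances are compared.
#'
#' @return data.frame with columns `pair`, `structure`, `intra_A`, `inter_A`,
#'   `source`.
#' @export
crystal_reference_distances <- function() {
  data.frame(
    pair = c("a-b", "b-c", "a-b", "b-c"),
    structure = c("rac-IbuH", "rac-IbuH", "S-IbuH", "S-IbuH"),
    intra_A = c(5.50, 6.61, 5.49, 6.21),
    inter_A = c(2.44, 4.98, 2.58, 3.17),
    source = "literature crystal structures"
  )
}

#' Compare dense-liquid NOE distances with crystal-contact distances
#'
#' Joins a NOE distance table (pairs labelled with dense-phase asterisks,
#' e.g. `"a*-b*"`) against the published intermolecular crystal contacts for
#' the corresponding proton-group pairs. Agreement of the liquid-phase
#' distances with the crystal contacts is the structural argument that the
#' dense liquid is a densified precursor in which crystalline order can
#' develop.
#'
#' @param noe_table Output of [noe_distance_table()].
#' @param reference Crystal reference table, by default
#'   [crystal_reference_distances()].
#' @return data.frame with the NOE distance and, per matching crystal
#'   structure, the intermolecular crystal distance and their difference.
#' @export
compare_noe_to_crystal <- function(noe_table,
                                   reference = crystal_reference_distances()) {
  stopifnot(is.data.frame(noe_table),
            all(c("pair", "distance_angstrom") %in% names(noe_table)))
  key <- gsub("\\*", "", noe_table$pair)
  out <- merge(
    data.frame(pair = key, noe_pair = noe_table$pair,
               noe_distance_A = noe_table$distance_angstrom),
    reference[, c("pair", "structure", "inter_A")],
    by = "pair"
  )
  out$difference_A <- out$noe_distance_A - out$inter_A
  out[order(out$pair, out$structure), ]
}
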