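#' Material property table
#'
#' A material table assigns MR-relevant physical properties to integer voxel
#' labels: magnetic susceptibility chi (ppm), relative proton density, a T1
#' model (either a constant in ms or a power-law dispersion T1 = A * B0^B),
#' a field-constant T2 (ms), and a no-signal flag for metals and other
#' signal-free solids.
#'
#' @param df data.frame with columns `material` (character), `label`
#'   (integer, unique), `chi_ppm`, `pd` (>= 0), `t1_type` ("const" or
#'   "power"), `t1_a_ms` (constant T1 or power-law A), `t1_b` (power-law
#'   exponent, ignored for "const"), `t2_ms` (> 0 where pd > 0), `is_metal`
#'   (logical; no MR signal, pd forced semantics pd = 0).
#' @return the validated data.frame with class `material_table`.
#' @export
material_table <- function(df) {
  need <- c("material", "label", "chi_ppm", "pd", "t1_type", "t1_a_ms",
            "t1_b", "t2_ms", "is_metal")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("material table missing columns: ",
                         paste(miss, collapse = ", "))
  df$label <- as.integer(df$label)
  if (anyDuplicated(df$label)) stop("duplicate labels in material table")
  if (anyDuplicated(df$material)) stop("duplicate material names")
  if (any(df$pd < 0)) stop("proton density must be >= 0")
  if (any(df$is_metal & df$pd != 0))
    stop("no-signal (metal) materials must have pd = 0")
  bearing <- df$pd > 0
  if (any(bearing & !(df$t2_ms > 0)))
    stop("t2_ms must be > 0 for signal-bearing materials")
  if (!all(df$t1_type %in% c("const", "power")))
    stop("t1_type must be 'const' or 'power'")
  if (any(bearing & !(df$t1_a_ms > 0)))
    stop("t1_a_ms must be > 0 for signal-bearing materials")
  class(df) <- c("material_table", "data.frame")
  df
}

material_row <- function(table, material) {
  i <- match(material, table$material)
  if (is.na(i)) stop("unknown material: ", material)
  table[i, , drop = FALSE]
}

#' Default material table
#'
#' Ships the susceptibility values used throughout the package: titanium
#' 182 ppm, cobalt-chromium 900 ppm, ceramic 2 ppm, polyethylene 9 ppm,
#' soft tissue and water -9.05 ppm, cortical bone -8.86 ppm, fat -5.55 ppm,
#' air 0.36 ppm. Proton density, T1 and T2 defaults are representative
#' literature-range values and are intended to be overridden by users with
#' their own measurements; T1 entries for tissues use the power-law
#' dispersion model, water uses a field-constant T1.
#'
#' @return a [material_table()].
#' @export
default_materials <- function() {
  material_table(data.frame(
    material = c("air", "water", "muscle", "fat", "cortical_bone",
                 "bone_marrow", "titanium", "cocr", "ceramic",
                 "polyethylene"),
    label    = c(0L, 1L, 2L, 3L, 4L, 5L, 10L, 11L, 12L, 13L),
    chi_ppm  = c(0.36, -9.05, -9.05, -5.55, -8.86, -5.55,
                 182, 900, 2, 9),
    pd       = c(0, 1.0, 0.7, 1.0, 0.15, 0.9, 0, 0, 0, 0),
    t1_type  = c("const", "const", "power", "power", "const", "power",
                 "const", "const", "const", "const"),
    t1_a_ms  = c(1, 3000, 900, 350, 250, 365, 1, 1, 1, 1),
    t1_b     = c(0, 0, 0.45, 0.20, 0, 0.20, 0, 0, 0, 0),
    t2_ms    = c(1, 2000, 35, 130, 0.5, 120, 1, 1, 1, 1),
    is_metal = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  ))
}

#' Read / write a material table as YAML
#'
#' Format: one map per material name with keys `label`, `chi_ppm`, `pd`,
#' `t1` (either `{const_ms: x}` or `{A: a, B: b}`), `t2_ms`, `is_metal`.
#'
#' @param table a [material_table()].
#' @param path file path.
#' @return `read_materials_yaml` returns a [material_table()];
#'   `write_materials_yaml` returns `path` invisibly.
#' @export
write_materials_yaml <- function(table, path) {
  out <- lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    t1 <- if (r$t1_type == "power") list(A = r$t1_a_ms, B = r$t1_b)
          else list(const_ms = r$t1_a_ms)
    list(label = r$label, chi_ppm = r$chi_ppm, pd = r$pd, t1 = t1,
         t2_ms = r$t2_ms, is_metal = r$is_metal)
  })
  names(out) <- table$material
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_materials_yaml
#' @export
read_materials_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(names(raw), function(nm) {
    r <- raw[[nm]]
    pow <- !is.null(r$t1$A)
    data.frame(material = nm, label = r$label, chi_ppm = r$chi_ppm,
               pd = r$pd,
               t1_type = if (pow) "power" else "const",
               t1_a_ms = if (pow) r$t1$A else r$t1$const_ms,
               t1_b = if (pow) r$t1$B else 0,
               t2_ms = r$t2_ms, is_metal = isTRUE(r$is_metal),
               stringsAsFactors = FALSE)
  })
  material_table(do.call(rbind, rows))
}
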