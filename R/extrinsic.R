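#' Extrinsic input/output tallies
#'
#' Counts connection records linking an intrinsic region set (for example
#' the condensed intrinsic network's leaves) with the rest of the nervous
#' system. For every intrinsic region twelve tallies are reported:
#' direct counts (`D*`) use records attached exactly at that region, while
#' subtree counts (`S*`) additionally aggregate records attached anywhere
#' in its subtree. `i`/`o` distinguishes inputs (the region is the target)
#' from outputs; the suffix `c`/`i` splits by contralateral/ipsilateral
#' laterality and `s` is their sum, so `Dis = Dic + Dii` by construction.
#' A record is extrinsic when its other endpoint lies outside the union of
#' the intrinsic regions' subtrees.
#'
#' @param records Validated record data.frame (see [read_records()]).
#' @param intrinsic Character vector of intrinsic region ids.
#' @param hierarchy A [region_hierarchy()] containing all intrinsic
#'   regions (record endpoints outside the hierarchy are treated as
#'   extrinsic leaves).
#' @return Data.frame with one row per intrinsic region and columns
#'   `region`, `Dic`, `Dii`, `Dis`, `Doc`, `Doi`, `Dos`,
#'   `Sic`, `Sii`, `Sis`, `Soc`, `Soi`, `Sos`.
#' @export
extrinsic_io_counts <- function(records, intrinsic, hierarchy) {
  records <- validate_records(as.data.frame(records))
  assert_region(hierarchy, intrinsic)
  scope <- lapply(intrinsic, function(r) subtree(hierarchy, r))
  names(scope) <- intrinsic
  intrinsic_scope <- unique(unlist(scope))
  contra <- records$laterality == "contralateral"
  src_ext <- !(records$source %in% intrinsic_scope)
  tgt_ext <- !(records$target %in% intrinsic_scope)

  tally <- function(attached_in, extrinsic_other, lat_contra) {
    c(sum(attached_in & extrinsic_other & lat_contra),
      sum(attached_in & extrinsic_other & !lat_contra))
  }
  rows <- lapply(intrinsic, function(r) {
    members <- scope[[r]]
    d_in <- tally(records$target == r, src_ext, contra)
    d_out <- tally(records$source == r, tgt_ext, contra)
    s_in <- tally(records$target %in% members, src_ext, contra)
    s_out <- tally(records$source %in% members, tgt_ext, contra)
    data.frame(region = r,
               Dic = d_in[1L], Dii = d_in[2L], Dis = sum(d_in),
               Doc = d_out[1L], Doi = d_out[2L], Dos = sum(d_out),
               Sic = s_in[1L], Sii = s_in[2L], Sis = sum(s_in),
               Soc = s_out[1L], Soi = s_out[2L], Sos = sum(s_out),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
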