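# Minimal explicit-VR little-endian DICOM writer, used only to build RT Plan
# fixtures at test time (binary fixtures are never shipped). Independent of
# the package's reader.

.w_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.w_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.w_pad <- function(bytes, pad) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

.w_long_vrs <- c("OB", "OW", "SQ", "UN", "UT")

w_elem <- function(group, element, vr, bytes) {
  bytes <- .w_pad(bytes, if (vr == "UI") as.raw(0L) else as.raw(0x20))
  head <- c(.w_u16(group), .w_u16(element), charToRaw(vr))
  if (vr %in% .w_long_vrs)
    c(head, as.raw(c(0, 0)), .w_u32(length(bytes)), bytes)
  else
    c(head, .w_u16(length(bytes)), bytes)
}

w_str <- function(group, element, vr, s) w_elem(group, element, vr, charToRaw(s))
w_ds <- function(group, element, nums)
  w_str(group, element, "DS", paste(sprintf("%.10g", nums), collapse = "\\"))
w_is <- function(group, element, nums)
  w_str(group, element, "IS", paste(sprintf("%d", as.integer(nums)), collapse = "\\"))

w_item <- function(bytes) c(.w_u16(0xFFFE), .w_u16(0xE000), .w_u32(length(bytes)), bytes)
w_sq <- function(group, element, items)
  w_elem(group, element, "SQ", do.call(c, c(lapply(items, w_item), list(raw(0)))))

# channels: list of lists with fields number, total_time, final_weight (or
# NULL), cps = list of list(pos = mm 3-vector, weight = numeric).
# points: list of list(name, pos_mm, dose_gy).
write_test_rtplan <- function(path, channels,
                              sk_U = 40700, half_life_days = 73.83,
                              cal_date = "20260901", plan_date = "20260915",
                              points = list(),
                              sop_class = "1.2.840.10008.5.1.4.1.1.481.5") {
  meta <- c(
    w_str(0x0002, 0x0002, "UI", sop_class),
    w_str(0x0002, 0x0003, "UI", "1.2.826.0.1.3680043.9999.1"),
    w_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))

  ch_items <- lapply(channels, function(ch) {
    cp_items <- lapply(ch$cps, function(cp) c(
      w_ds(0x300A, 0x02D4, cp$pos),
      w_ds(0x300A, 0x02D6, cp$weight)))
    body <- c(
      w_is(0x300A, 0x0282, ch$number),
      w_ds(0x300A, 0x0286, ch$total_time),
      if (!is.null(ch$final_weight)) w_ds(0x300A, 0x02C8, ch$final_weight),
      w_is(0x300A, 0x0110, length(ch$cps)),
      w_sq(0x300A, 0x02D0, cp_items))
    body
  })

  pt_items <- lapply(points, function(p) c(
    w_str(0x300A, 0x0016, "LO", p$name),
    w_ds(0x300A, 0x0018, p$pos_mm),
    w_ds(0x300A, 0x0026, p$dose_gy)))

  dataset <- c(
    w_str(0x0008, 0x0016, "UI", sop_class),
    w_str(0x0008, 0x0018, "UI", "1.2.826.0.1.3680043.9999.2"),
    w_str(0x300A, 0x0002, "SH", "fixture-plan"),
    w_str(0x300A, 0x0006, "DA", plan_date),
    if (length(pt_items)) w_sq(0x300A, 0x0010, pt_items) else raw(0),
    w_sq(0x300A, 0x0210, list(c(
      w_ds(0x300A, 0x0226, half_life_days),
      w_ds(0x300A, 0x022A, sk_U),
      w_str(0x300A, 0x022C, "DA", cal_date)))),
    w_sq(0x300A, 0x0230, list(w_sq(0x300A, 0x0280, ch_items))))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

# straight channel along +z: n dwells, 10 s each, step mm apart, paired with
# a leading zero-weight control point at the first position
straight_channel <- function(n = 3, step_mm = 5, t_each = 10, number = 1) {
  cps <- list(list(pos = c(0, 0, 0), weight = 0))
  for (i in seq_len(n))
    cps[[i + 1L]] <- list(pos = c(0, 0, (i - 1) * step_mm), weight = i)
  list(number = number, total_time = n * t_each, final_weight = n, cps = cps)
}
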