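# PSQI component scoring cut-points.
#
# Defaults follow the published scoring manual of the instrument; the whole
# table is configuration so that scoring dialects can be swapped without
# code changes. Bands are applied as documented next to each entry.
latency:
  # reported minutes-to-fall-asleep band: <=15 -> 0, 16-30 -> 1,
  # 31-60 -> 2, >60 -> 3
  minutes_upper: [15, 30, 60]
  # band + frequency item (0-3) combined: 0 -> 0, 1-2 -> 1, 3-4 -> 2, 5-6 -> 3
  sum_upper: [0, 2, 4]
duration:
  # reported hours: >7 -> 0, 6-7 -> 1, 5-6 -> 2, <5 -> 3 (lower bounds,
  # inclusive at 6 and 5)
  hours_lower: [7, 6, 5]
efficiency:
  # percent sleep duration / time in bed: >=85 -> 0, 75-84 -> 1,
  # 65-74 -> 2, <65 -> 3
  percent_lower: [85, 75, 65]
disturbance:
  # sum of the nine disturbance frequency items (0-27):
  # 0 -> 0, 1-9 -> 1, 10-18 -> 2, 19-27 -> 3
  sum_upper: [0, 9, 18]
daytime:
  # sleepiness + enthusiasm items (0-6): 0 -> 0, 1-2 -> 1, 3-4 -> 2, 5-6 -> 3
  sum_upper: [0, 2, 4]
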