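# Default frame geometry and simulation presets.
#
# The localizer dimensions below are configurable working defaults for
# a Zamorano-Dujovny-style frame, not measured hardware dimensions.
# All lengths in millimeters, angles in degrees.

frames:
  sp3:
    type: sp
    aspects: [anterior, left, right]
    radius_mm: 100
    tan_alpha: 0.8
    extent_mm: 190
  sp4:
    type: sp
    aspects: [anterior, left, right, posterior]
    radius_mm: 100
    tan_alpha: 0.8
    extent_mm: 190
  n4:
    type: n
    aspects: [anterior, left, right, posterior]
    radius_mm: 100
    n_width_mm: 120
    n_height_mm: 140

noise:
  max_magnitude_mm: 1.0
  distribution: disk_uniform

# Scenario presets: the classic one-point solve against the
# three-point solve on the 3- and 4-localizer SP frames at 0 and 10
# degree tilt, plus the four-N-localizer comparison arm. Tilted
# sweeps start higher so the scan plane clears the frame base.
scenarios:
  fig3:
    frame: sp3
    modes: [classic, three_point]
    theta_deg: 0
    z_min_mm: 5
    z_max_mm: 155
    z_step_mm: 2
  fig4:
    frame: sp3
    modes: [classic, three_point]
    theta_deg: 10
    z_min_mm: 21
    z_max_mm: 155
    z_step_mm: 2
  fig5:
    frame: sp4
    modes: [classic, three_point]
    theta_deg: 0
    z_min_mm: 5
    z_max_mm: 155
    z_step_mm: 2
  fig6:
    frame: sp4
    modes: [classic, three_point]
    theta_deg: 10
    z_min_mm: 27
    z_max_mm: 155
    z_step_mm: 2
  fig7_sp:
    frame: sp4
    modes: [three_point]
    theta_deg: 10
    z_min_mm: 27
    z_max_mm: 155
    z_step_mm: 2
  fig7_n:
    frame: n4
    modes: [n_localizer]
    theta_deg: 0
    z_min_mm: 10
    z_max_mm: 130
    z_step_mm: 2
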