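# Approximate M20iA-class 6R manipulator (~1.8 m reach).
# The vendor does not publish DH parameters; these are an approximation
# assembled from published reach/limit datasheets and are intended as a
# realistic default, not a metrologically accurate twin.
# dh rows: [a_m, alpha_deg, d_m, theta_offset_deg]  (standard DH)
name: m20ia-like
dh:
  - [0.150, -90.0, 0.525, 0.0]
  - [0.790, 180.0, 0.000, -90.0]
  - [0.250, -90.0, 0.000, 180.0]
  - [0.000, 90.0, 0.835, 0.0]
  - [0.000, -90.0, 0.000, 0.0]
  - [0.000, 180.0, 0.100, 0.0]
joint_limits_deg:
  - [-185.0, 185.0]
  - [-100.0, 160.0]
  - [-180.0, 260.0]
  - [-200.0, 200.0]
  - [-180.0, 180.0]
  - [-450.0, 450.0]
velocity_limits_deg_s:
  - 195.0
  - 175.0
  - 180.0
  - 360.0
  - 360.0
  - 550.0
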