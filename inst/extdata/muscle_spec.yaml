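# Four wrist prime movers: preferred directions (cursor-space degrees,
# right = 0, up = 90) and admissible weight signs per axis.
# x: flexion/extension axis (extension positive); y: deviation axis
# (radial positive).
muscles:
  - name: ECR
    pd_deg: 68
    sign_x: 1
    sign_y: 1
  - name: ECU
    pd_deg: 125
    sign_x: 1
    sign_y: -1
  - name: FCU
    pd_deg: 189
    sign_x: -1
    sign_y: -1
  - name: FCR
    pd_deg: 265
    sign_x: -1
    sign_y: 1
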