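- if:
    hr: Normal
    ct: Normal
  op: and
  not: []
  then: Safe
- if:
    hr: Caution
    ct: Normal
  op: and
  not: []
  then: Concern
- if:
    hr: Danger
    ct: Normal
  op: and
  not: []
  then: Attention
- if:
    ct: Low
  op: and
  not: []
  then: Concern
- if:
    hr: Danger
    ct: Low
  op: and
  not: []
  then: Attention
- if:
    ct: TooLow
  op: and
  not: []
  then: Attention
- if:
    ct: High
  op: and
  not: []
  then: Attention
- if:
    ct: TooHigh
  op: and
  not: []
  then: Danger
- if:
    hr: Caution
    ct: Normal
    t: Attention
  op: and
  not: []
  then: Attention
- if:
    hr: Caution
    ct: Normal
    t: Danger
  op: and
  not: []
  then: Attention
- if:
    hr: Danger
    ct: Normal
    t: Attention
  op: and
  not: []
  then: Danger
- if:
    hr: Danger
    ct: Normal
    t: Danger
  op: and
  not: []
  then: Danger
- if:
    ct: Low
    t: Attention
  op: and
  not: []
  then: Attention
- if:
    ct: Low
    t: Danger
  op: and
  not: []
  then: Attention
- if:
    hr: Danger
    ct: Low
    t: Attention
  op: and
  not: []
  then: Danger
- if:
    hr: Danger
    ct: Low
    t: Danger
  op: and
  not: []
  then: Danger
- if:
    ct: TooLow
    t: Attention
  op: and
  not: []
  then: Danger
- if:
    ct: TooLow
    t: Danger
  op: and
  not: []
  then: Danger
- if:
    ct: High
    t: Attention
  op: and
  not: []
  then: Danger
- if:
    ct: High
    t: Danger
  op: and
  not: []
  then: Danger
- if:
    hr: Danger
    ct: TooHigh
  op: or
  not: []
  then: Danger
- if:
    w: High
    hr: Caution
    t: Safe
  op: and
  not:
  - t
  then: Attention
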