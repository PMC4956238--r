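- item_id: 5
  scale_min: 1
  scale_max: 6
  inverted: no
  doubled: yes
  checkbox_allowed: no
- item_id: 6
  scale_min: 1
  scale_max: 10
  inverted: no
  doubled: no
  checkbox_allowed: no
- item_id: 7
  scale_min: 1
  scale_max: 10
  inverted: no
  doubled: no
  checkbox_allowed: no
- item_id: 8
  scale_min: 0
  scale_max: 10
  inverted: no
  doubled: no
  checkbox_allowed: yes
- item_id: 9
  scale_min: 0
  scale_max: 10
  inverted: no
  doubled: no
  checkbox_allowed: no
- item_id: 10
  scale_min: 0
  scale_max: 10
  inverted: no
  doubled: no
  checkbox_allowed: no
- item_id: 11
  scale_min: 0
  scale_max: 10
  inverted: no
  doubled: no
  checkbox_allowed: no
- item_id: 12
  scale_min: 0
  scale_max: 10
  inverted: yes
  doubled: no
  checkbox_allowed: no
- item_id: 13
  scale_min: 0
  scale_max: 10
  inverted: no
  doubled: no
  checkbox_allowed: no
- item_id: 14
  scale_min: 0
  scale_max: 10
  inverted: no
  doubled: no
  checkbox_allowed: no
- item_id: 15
  scale_min: 0
  scale_max: 10
  inverted: no
  doubled: no
  checkbox_allowed: no
- item_id: 16
  scale_min: 0
  scale_max: 10
  inverted: yes
  doubled: no
  checkbox_allowed: yes
- item_id: 17
  scale_min: 0
  scale_max: 10
  inverted: yes
  doubled: no
  checkbox_allowed: yes
- item_id: 18
  scale_min: 0
  scale_max: 10
  inverted: no
  doubled: no
  checkbox_allowed: no
- item_id: 19
  scale_min: 0
  scale_max: 10
  inverted: no
  doubled: no
  checkbox_allowed: no
- item_id: 20
  scale_min: 0
  scale_max: 10
  inverted: no
  doubled: no
  checkbox_allowed: no
- item_id: 21
  scale_min: 0
  scale_max: 10
  inverted: yes
  doubled: no
  checkbox_allowed: no
- item_id: 22
  scale_min: 0
  scale_max: 10
  inverted: yes
  doubled: no
  checkbox_allowed: no
- item_id: 23
  scale_min: 0
  scale_max: 10
  inverted: yes
  doubled: no
  checkbox_allowed: no
- item_id: 24
  scale_min: 0
  scale_max: 10
  inverted: yes
  doubled: no
  checkbox_allowed: no
- item_id: 25
  scale_min: 0
  scale_max: 10
  inverted: yes
  doubled: no
  checkbox_allowed: no
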