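# Representative adult-rat geometry; same values as default_geometry()
thigh_length = 40
shank_length = 40
crank_length = 25
ankle_pedal_horizontal = 10
ankle_pedal_vertical = 5
hip_offset_x = 0
hip_offset_y = 50
pedal_rod_distance = 60
crank_zero_offset_deg = 0
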