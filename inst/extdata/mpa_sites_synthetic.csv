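name,lat,lon
subpolar_north_pacific,45,-150
california_current,35,-125
caribbean_reef,17,-67
coral_triangle,-5,125
equatorial_pacific,-1,-165
south_subtropical_atlantic,-30,-20
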