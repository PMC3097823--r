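concept	taxon	cognate_class	loan
tooth	English	c1	FALSE
tooth	German	c1	FALSE
tooth	Italian	c2	FALSE
tooth	French	c2	FALSE
tooth	Russian	c3	FALSE
tooth	Polish	c3	FALSE
mountain	English	c1	TRUE
mountain	Italian	c1	FALSE
mountain	French	c1	FALSE
mountain	German	c2	FALSE
mountain	Russian	c3	FALSE
mountain	Polish	c3	FALSE
water	English	c1	FALSE
water	German	c1	FALSE
water	Russian	c1	FALSE
water	Polish	c1	FALSE
water	Italian	c2	FALSE
water	French	c2	FALSE
hand	English	c1	FALSE
hand	German	c1	FALSE
hand	Italian	c2	FALSE
hand	French	c2	FALSE
hand	Russian	c2	TRUE
hand	Polish	c3	FALSE
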