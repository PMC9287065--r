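{"food_area":[760,504,1288,1032],"end_area":{"left":[227,568,587,968],"right":[1461,568,1821,968],"top":[824,151,1224,331],"bottom":[824,1205,1224,1385]},"screen":[2048,1536],"ppi":[326]}
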