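fish_class,description,grams
white,"Plaice in batter, fried",50
white,"Cod fillets, baked",30
white,"Haddock in crumbs, fried",30
white,"Fish fingers, grilled",20
oily,"Tuna, canned in brine",60
oily,"Salmon fish cakes, homemade",12
oily,"Pink salmon, canned",10
oily,"Brown trout",8
oily,"Salmon, steamed",5
oily,"Sardines, canned in oil",5
oily,"Pilchards, canned in tomato sauce",5
oily,"Sardines, canned in tomato sauce",3
shellfish,"Scampi, breadcrumbed and fried",43
shellfish,"Crab, canned",21
shellfish,"Mussels, boiled",10
shellfish,"Prawns, boiled",15
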