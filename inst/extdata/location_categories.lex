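# name: location_categories
# version: 1.0
# Eleven location categories for vaping-related social-media surveillance.
# Keywords are stored in lowercase lemma form; the classifier matches whole
# tokens after lemmatization, so plural and inflected surface forms
# ("cars", "driving", "parties") match their base keyword.

[Social venues]
game
party
park
beach
club
concert
festival

[Living space]
home
bedroom
hotel
house
apartment

[Stores]
shop
store
market
gym
mall

[Modes of transportation]
car
drive
train
bus
subway
plane

[School]
school
class
college
classroom
campus

[Workplace]
work
job
workplace
office

[Healthcare offices]
doctor
dentist
drugstore
hospital
clinic
pharmacy

[Eateries]
restaurant
café
cafe
boba
diner

[Correctional facility]
court
prison
jail

[Religious institutions]
church
chapel
temple
mosque

[Miscellaneous]
place
town
downtown
neighborhood
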